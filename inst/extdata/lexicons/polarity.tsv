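# Polarity-reversal lexicon: form <TAB> pos <TAB> weight (-1 = reversal)
decreased	ADJ	-1
decrease	NOUN	-1
reduced	ADJ	-1
reduction	NOUN	-1
loss	NOUN	-1
knockdown	NOUN	-1
silencing	NOUN	-1
inhibition	NOUN	-1
suppression	NOUN	-1
depletion	NOUN	-1
depleted	ADJ	-1
deficiency	NOUN	-1
deficient	ADJ	-1
absence	NOUN	-1
lack	NOUN	-1
downregulation	NOUN	-1
impaired	ADJ	-1
diminished	ADJ	-1
defective	ADJ	-1
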