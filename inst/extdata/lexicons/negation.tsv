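# Negation cues: one lower-cased form per line
not
no
n't
never
cannot
without
unable
fail
fails
failed
neither
nor
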