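# Trigger lexicon: label <TAB> lemma <TAB> pos. Verb lemmas are inflected at
# load time; noun lemmas gain plurals. Removal (de-) events mirror additions.
phosphorylation	phosphorylate	verb
phosphorylation	phosphorylation	noun
ubiquitination	ubiquitinate	verb
ubiquitination	ubiquitination	noun
hydroxylation	hydroxylate	verb
hydroxylation	hydroxylation	noun
sumoylation	sumoylate	verb
sumoylation	sumoylation	noun
glycosylation	glycosylate	verb
glycosylation	glycosylation	noun
acetylation	acetylate	verb
acetylation	acetylation	noun
farnesylation	farnesylate	verb
farnesylation	farnesylation	noun
ribosylation	ribosylate	verb
ribosylation	ribosylation	noun
methylation	methylate	verb
methylation	methylation	noun
dephosphorylation	dephosphorylate	verb
dephosphorylation	dephosphorylation	noun
deubiquitination	deubiquitinate	verb
deubiquitination	deubiquitination	noun
dehydroxylation	dehydroxylate	verb
dehydroxylation	dehydroxylation	noun
desumoylation	desumoylate	verb
desumoylation	desumoylation	noun
deglycosylation	deglycosylate	verb
deglycosylation	deglycosylation	noun
deacetylation	deacetylate	verb
deacetylation	deacetylation	noun
defarnesylation	defarnesylate	verb
defarnesylation	defarnesylation	noun
deribosylation	deribosylate	verb
deribosylation	deribosylation	noun
demethylation	demethylate	verb
demethylation	demethylation	noun
binding	bind	verb
binding	interact	verb
binding	associate	verb
binding	dimerize	verb
binding	binding	noun
binding	interaction	noun
binding	association	noun
binding	complex	noun
binding	heterodimer	noun
hydrolysis	hydrolyze	verb
hydrolysis	degrade	verb
hydrolysis	cleave	verb
hydrolysis	hydrolysis	noun
hydrolysis	degradation	noun
hydrolysis	cleavage	noun
translocation	translocate	verb
translocation	transport	verb
translocation	relocate	verb
translocation	localize	verb
translocation	accumulate	verb
translocation	translocation	noun
translocation	transport	noun
translocation	relocation	noun
translocation	localization	noun
positive_regulation	activate	verb
positive_regulation	enhance	verb
positive_regulation	promote	verb
positive_regulation	increase	verb
positive_regulation	induce	verb
positive_regulation	stimulate	verb
positive_regulation	cause	verb
positive_regulation	accelerate	verb
positive_regulation	upregulate	verb
positive_regulation	mediate	verb
positive_regulation	result	verb
positive_regulation	lead	verb
positive_regulation	activation	noun
positive_regulation	induction	noun
positive_regulation	stimulation	noun
positive_regulation	upregulation	noun
negative_regulation	inhibit	verb
negative_regulation	block	verb
negative_regulation	suppress	verb
negative_regulation	decrease	verb
negative_regulation	reduce	verb
negative_regulation	attenuate	verb
negative_regulation	impair	verb
negative_regulation	diminish	verb
negative_regulation	abolish	verb
negative_regulation	repress	verb
negative_regulation	downregulate	verb
negative_regulation	prevent	verb
negative_regulation	inhibition	noun
negative_regulation	suppression	noun
negative_regulation	blockade	noun
negative_regulation	downregulation	noun
negative_regulation	repression	noun
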