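# Synthetic knowledge-base fixture: namespace, identifier, canonical, synonyms (|-separated), entity_type.
# Identifiers are illustrative; this is test/demo data, not a curated resource.
uniprot	Q02750	MAP2K1	MEK1|MEK|MAP kinase kinase 1	gene_or_gene_product
uniprot	P28482	MAPK1	ERK|ERK2	gene_or_gene_product
uniprot	P27361	MAPK3	ERK1	gene_or_gene_product
uniprot	P61586	RHOA	RhoA	gene_or_gene_product
uniprot	Q9HCE7	SMURF1	Smurf1	gene_or_gene_product
uniprot	Q9HAU4	SMURF2	Smurf2	gene_or_gene_product
uniprot	P01116	KRAS	K-Ras|Ras	gene_or_gene_product
uniprot	P04637	TP53	p53	gene_or_gene_product
uniprot	Q12923	PTPN13	PTP-BL	gene_or_gene_product
uniprot	P98172	EFNB1	EphrinB1|Ephrin-B1	gene_or_gene_product
uniprot	P16104	H2AX	histone H2AX|H2AFX	gene_or_gene_product
uniprot	Q13185	CBX3	HP1-gamma|HP1 gamma	gene_or_gene_product
uniprot	O14641	DVL2	Dvl2	gene_or_gene_product
uniprot	Q05513	PRKCZ	aPKC|PKC-zeta	gene_or_gene_product
uniprot	P21580	TNFAIP3	A20	gene_or_gene_product
uniprot	Q15025	TNIP1	ABIN|ABIN-1	gene_or_gene_product
uniprot	P08069	IGF1R	IGF-1R	gene_or_gene_product
uniprot	P49913	LL-37	CAP-18|cathelicidin	gene_or_gene_product
uniprot	O00408	PDE2A	Pde2	gene_or_gene_product
uniprot	P02741	CRP	C-reactive protein	gene_or_gene_product
uniprot	O14965	AURKA	Aurora A|Aurora-A	gene_or_gene_product
uniprot	P60953	CDC42	Cdc42	gene_or_gene_product
uniprot	Q16539	MAPK14	p38|p38 alpha	gene_or_gene_product
uniprot	P42336	PIK3CA	PI3K alpha	gene_or_gene_product
uniprot	P31749	AKT1	Akt1|Akt	gene_or_gene_product
uniprot	P04049	RAF1	Raf-1|c-Raf	gene_or_gene_product
uniprot	P00533	EGFR	ErbB1|HER1	gene_or_gene_product
uniprot	P38398	BRCA1	BRCA1	gene_or_gene_product
uniprot	P06400	RB1	pRb|Rb	gene_or_gene_product
uniprot	P60484	PTEN	PTEN	gene_or_gene_product
uniprot	P23771	GATA3	GATA3	gene_or_gene_product
uaz	UAZ-EHR	EHR		gene_or_gene_product
interpro	IPR003527	MAPK family	MAP kinase family|p38	family
interpro	IPR005817	Wnt family	Wnt	family
interpro	IPR000719	protein kinase family	kinase family	family
chebi	CHEBI:17489	cAMP	cyclic AMP|3',5'-cyclic AMP	simple_chemical
chebi	CHEBI:15422	ATP	adenosine triphosphate	simple_chemical
chebi	CHEBI:17552	GDP	guanosine diphosphate	simple_chemical
chebi	CHEBI:33216	BPA	bisphenol A	simple_chemical
hmdb	HMDB0000058	cAMP	cyclic AMP	simple_chemical
hmdb	HMDB0000538	ATP		simple_chemical
go	GO:0005634	nucleus		cellular_component
go	GO:0005737	cytoplasm		cellular_component
go	GO:0005886	plasma membrane	cell membrane	cellular_component
go	GO:0005739	mitochondrion	mitochondria	cellular_component
go	GO:0005794	Golgi apparatus	Golgi	cellular_component
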