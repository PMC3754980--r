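id	name	formula	mass	pathway
gca	Glycocholic acid	C26H43NO6		bile acid biosynthesis
gdca	Glycodeoxycholic acid	C26H43NO5		bile acid biosynthesis
gudca	Glycoursodeoxycholic acid	C26H43NO5		bile acid biosynthesis
ca	Cholic acid	C24H40O5		bile acid biosynthesis
acphe	Acetylphenylalanine	C11H13NO3		tyrosine metabolism
actrp	Acetyltryptophan	C13H14N2O3		tryptophan metabolism
phe	Phenylalanine	C9H11NO2		tyrosine metabolism
tyr	Tyrosine	C9H11NO3		tyrosine metabolism
gln	Glutamine	C5H10N2O3		urea cycle
asp	Aspartate	C4H7NO4		urea cycle
glu	Glutamate	C5H9NO4		urea cycle
cys	Cysteine	C3H7NO2S		sulfur amino acid metabolism
hcys	Homocysteine	C4H9NO2S		sulfur amino acid metabolism
met	Methionine	C5H11NO2S		sulfur amino acid metabolism
glc	Hexose	C6H12O6		galactose metabolism
adenosine	Adenosine	C10H13N5O4		purine metabolism
panto	Pantothenate	C9H17NO5		CoA biosynthesis
chol	Cholesterol	C27H46O		steroid biosynthesis
testost	Testosterone	C19H28O2		steroid biosynthesis
citr	Citrulline	C6H13N3O3		urea cycle
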