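# Verbatim drug name -> ingredient (tab-separated). Brand names,
# international names and common misspellings; extend freely. A value of
# EXCLUDE drops the record as ambiguous.
avandia	rosiglitazone
avandamet	rosiglitazone and metformin
actos	pioglitazone
glucophage	metformin
metformin hcl	metformin
onglyza	saxagliptin
kombiglyze	metformin and saxagliptin
kombiglyze xr	metformin and saxagliptin
humalog	insulin lispro
entresto	sacubitril and valsartan
sacubitril/valsartan	sacubitril and valsartan
humira	adalimumab
vioxx	rofecoxib
letairis	ambrisentan
volibris	ambrisentan
aggrastat	tirofiban
adriamycin	doxorubicin
doxorubicin hydrochloride	doxorubicin
kyprolis	carfilzomib
vyndaqel	tafamidis
vyndamax	tafamidis
opsumit	macitentan
remodulin	treprostinil
pradaxa	dabigatran
dabigatran etexilate	dabigatran
eliquis	apixaban
lipitor	atorvastatin
atorvastatin calcium	atorvastatin
effexor	venlafaxine
venlafaxine hydrochloride	venlafaxine
gleevec	imatinib
imatinib mesylate	imatinib
keytruda	pembrolizumab
velcade	bortezomib
opdivo	nivolumab
avastin	bevacizumab
herceptin	trastuzumab
tagrisso	osimertinib
prilosec	omeprazole
prinivil	lisinopril
zestril	lisinopril
lanoxin	digoxin
lasix	furosemide
unknown medication	EXCLUDE
unspecified drug	EXCLUDE
multiple drugs	EXCLUDE
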