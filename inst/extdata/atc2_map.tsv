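# Ingredient -> WHO ATC level-2 class (tab-separated); several rows per
# ingredient allowed. Checked against the public WHO ATC index.
rosiglitazone	A10
pioglitazone	A10
metformin	A10
rosiglitazone and metformin	A10
saxagliptin	A10
metformin and saxagliptin	A10
insulin lispro	A10
omeprazole	A02
sacubitril and valsartan	C09
lisinopril	C09
valsartan	C09
ambrisentan	C02
macitentan	C02
atorvastatin	C10
digoxin	C01
furosemide	C03
tirofiban	B01
treprostinil	B01
dabigatran	B01
apixaban	B01
doxorubicin	L01
carfilzomib	L01
pembrolizumab	L01
bortezomib	L01
nivolumab	L01
imatinib	L01
bevacizumab	L01
trastuzumab	L01
osimertinib	L01
adalimumab	L04
rofecoxib	M01
venlafaxine	N06
tafamidis	N07
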