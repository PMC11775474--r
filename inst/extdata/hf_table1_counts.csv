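section,band,count
Sex,Male,94264
Sex,Female,100658
Sex,Unknown,21440
Age,<18,4376
Age,18 >= and <65,66722
Age,65 >= and <85,68625
Age,>=85,9535
Age,Unknown,67104
Weight,<50,7004
Weight,50 >= and <100,44470
Weight,>=100,11190
Weight,Unknown,153698
Occupation,Healthcare professional,134873
Occupation,Non-healthcare professional,70687
Occupation,Unknown,10802
Country,United States,99942
Country,Japan,14919
Country,France,11016
Country,Canada,8457
Country,Germany,8137
Country,United Kingdom,6939
Country,Others,66952
Outcome,Hospitalization,88164
Outcome,Death,63442
Outcome,Other Serious Outcome,42172
Outcome,Life-threatening,14422
Outcome,Disability,926
Outcome,Unknown,7236
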