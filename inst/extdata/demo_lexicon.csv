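surface_form,concept_id,name,semantic_type
abd pain,C0000737,abdominal pain,Sign or Symptom
abdominal pain,C0000737,abdominal pain,Sign or Symptom
nausea,C0027497,nausea,Sign or Symptom
vomiting,C0042963,vomiting,Sign or Symptom
chest pain,C0008031,chest pain,Sign or Symptom
shortness of breath,C0013404,dyspnea,Sign or Symptom
tension,C0233494,tension,Sign or Symptom
opioid use disorder,C4324621,opioid use disorder,Mental or Behavioral Dysfunction
alcohol use disorder,C0001973,alcohol use disorder,Mental or Behavioral Dysfunction
depression,C0011570,depression,Mental or Behavioral Dysfunction
opioid overdose,C0029095,opioid overdose,Injury or Poisoning
hypertension,C0020538,hypertensive disease,Disease or Syndrome
diabetes mellitus,C0011849,diabetes mellitus,Disease or Syndrome
cirrhosis,C0023890,liver cirrhosis,Disease or Syndrome
cellulitis,C0007642,cellulitis,Disease or Syndrome
altered mental status,C0856054,altered mental status,Finding
suicidal ideation,C0424000,suicidal ideation,Finding
tachycardia,C0039231,tachycardia,Finding
lumbar puncture,C0037943,lumbar puncture,Diagnostic Procedure
psychiatric evaluation,C0846574,psychiatric evaluation,Diagnostic Procedure
urine drug screen,C0430377,urine drug screen,Laboratory Procedure
blood culture,C0200949,blood culture,Laboratory Procedure
intubation,C0021925,endotracheal intubation,Therapeutic or Preventive Procedure
naloxone,C0027358,naloxone,Pharmacologic Substance
methadone,C0025605,methadone,Pharmacologic Substance
buprenorphine,C0006405,buprenorphine,Pharmacologic Substance
heroin,C0011892,heroin,Pharmacologic Substance
acetaminophen 325 mg oral tablet,C0987225,acetaminophen 325 mg oral tablet,Clinical Drug
liver,C0023884,liver,"Body Part, Organ, or Organ Component"
lumbar spine,C0024091,lumbar spine,Anatomical Structure
new haven,C0027784,new haven,Geographic Area
emergency department,C0562508,emergency department,Health Care Related Organization
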