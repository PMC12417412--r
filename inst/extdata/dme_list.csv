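pt_name
ACUTE HEPATIC FAILURE
ACUTE KIDNEY INJURY
ACUTE RESPIRATORY DISTRESS SYNDROME
AGRANULOCYTOSIS
ANAPHYLACTIC REACTION
ANAPHYLACTIC SHOCK
ANAPHYLACTOID REACTION
ANAPHYLACTOID SHOCK
ANGIOEDEMA
APLASTIC ANAEMIA
AUTOIMMUNE HAEMOLYTIC ANAEMIA
AUTOIMMUNE HEPATITIS
AZOTAEMIA
BLINDNESS
BONE MARROW FAILURE
DEAFNESS
DEAFNESS NEUROSENSORY
DEAFNESS PERMANENT
DEAFNESS TRANSITORY
DRUG REACTION WITH EOSINOPHILIA AND SYSTEMIC SYMPTOMS
DRUG-INDUCED LIVER INJURY
ERYTHEMA MULTIFORME
FEBRILE NEUTROPENIA
FULMINANT HEPATITIS
GRANULOCYTOPENIA
GUILLAIN-BARRE SYNDROME
HAEMOLYSIS
HAEMOLYTIC ANAEMIA
HEPATIC FAILURE
HEPATIC INFARCTION
HEPATIC NECROSIS
HEPATORENAL FAILURE
HEPATORENAL SYNDROME
INTESTINAL PERFORATION
NEUROLEPTIC MALIGNANT SYNDROME
NEUTROPENIC COLITIS
NEUTROPENIC INFECTION
NEUTROPENIC SEPSIS
OTOTOXICITY
PANCREATITIS
PANCREATITIS ACUTE
PANCREATITIS HAEMORRHAGIC
PANCREATITIS NECROTISING
PANCYTOPENIA
PRODUCT CONTAMINATION MICROBIAL
PROGRESSIVE MULTIFOCAL LEUKOENCEPHALOPATHY
PULMONARY ARTERIAL HYPERTENSION
PULMONARY FIBROSIS
PULMONARY HYPERTENSION
PURE RED CELL APLASIA
RENAL FAILURE
RESPIRATORY FAILURE
REYES SYNDROME
RHABDOMYOLYSIS
STEVENS-JOHNSON SYNDROME
SUDDEN CARDIAC DEATH
SUDDEN DEATH
SUDDEN HEARING LOSS
TORSADE DE POINTES
TOXIC EPIDERMAL NECROLYSIS
TRANSPLANT REJECTION
VENTRICULAR FIBRILLATION
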