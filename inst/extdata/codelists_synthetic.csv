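role,condition,code,system,window_kind,window_length,status,is_history
disease,Bullous pemphigoid,L12.0,ICD10,ANY_BEFORE,,,FALSE
disease,Bullous pemphigoid,L12.9,ICD10,ANY_BEFORE,,,FALSE
disease,Bullous pemphigoid,M145.,READ,ANY_BEFORE,,,FALSE
disease,Bullous pemphigoid,M145.00,READ,ANY_BEFORE,,,FALSE
disease,Bullous pemphigoid,M145z00,READ,ANY_BEFORE,,,FALSE
dementia,Dementia,DE01.,READ,ANY_BEFORE,,,FALSE
dementia,Dementia,DE02.,READ,ANY_BEFORE,,,FALSE
dementia,Dementia,F00.9,ICD10,ANY_BEFORE,,,FALSE
dementia,Dementia,F03,ICD10,ANY_BEFORE,,,FALSE
caution,Diabetes mellitus,DM01.,READ,ANY_BEFORE,,WITH_CAUTION,FALSE
caution,Diabetes mellitus,DM02.,READ,ANY_BEFORE,,WITH_CAUTION,FALSE
caution,Diabetes mellitus,DMHX.,READ,ANY_BEFORE,,WITH_CAUTION,TRUE
caution,Diabetes mellitus,Z01.1,ICD10,ANY_BEFORE,,WITH_CAUTION,FALSE
caution,Diverticulitis,DV01.,READ,YEARS_BEFORE,1,POSSIBLE,FALSE
caution,Diverticulitis,DV02.,READ,YEARS_BEFORE,1,POSSIBLE,FALSE
caution,Diverticulitis,Z02.2,ICD10,YEARS_BEFORE,1,POSSIBLE,FALSE
caution,Epilepsy,EP01.,READ,ANY_BEFORE,,POSSIBLE,FALSE
caution,Epilepsy,EP02.,READ,ANY_BEFORE,,POSSIBLE,FALSE
caution,Epilepsy,Z03.3,ICD10,ANY_BEFORE,,POSSIBLE,FALSE
caution,Glaucoma,GL01.,READ,ANY_BEFORE,,WITH_CAUTION,FALSE
caution,Glaucoma,GL02.,READ,ANY_BEFORE,,WITH_CAUTION,FALSE
caution,Glaucoma,Z04.4,ICD10,ANY_BEFORE,,WITH_CAUTION,FALSE
caution,Heart failure,HF01.,READ,ANY_BEFORE,,WITH_CAUTION,FALSE
caution,Heart failure,HF02.,READ,ANY_BEFORE,,WITH_CAUTION,FALSE
caution,Heart failure,Z05.5,ICD10,ANY_BEFORE,,WITH_CAUTION,FALSE
caution,Hypertension,HT01.,READ,ANY_BEFORE,,POSSIBLE,FALSE
caution,Hypertension,HT02.,READ,ANY_BEFORE,,POSSIBLE,FALSE
caution,Hypertension,Z06.6,ICD10,ANY_BEFORE,,POSSIBLE,FALSE
caution,Hypothyroidism,HY01.,READ,ANY_BEFORE,,POSSIBLE,FALSE
caution,Hypothyroidism,HY02.,READ,ANY_BEFORE,,POSSIBLE,FALSE
caution,Hypothyroidism,Z07.7,ICD10,ANY_BEFORE,,POSSIBLE,FALSE
caution,Intestinal anastomosis,G741,OPCS,MONTHS_BEFORE,6,UNLIKELY,FALSE
caution,Intestinal anastomosis,IA01.,READ,MONTHS_BEFORE,6,UNLIKELY,FALSE
caution,Intestinal anastomosis,IA02.,READ,MONTHS_BEFORE,6,UNLIKELY,FALSE
caution,Intestinal anastomosis,Z08.8,ICD10,MONTHS_BEFORE,6,UNLIKELY,FALSE
caution,Malignancy (excluding BCC),MG01.,READ,YEARS_BEFORE,5,POSSIBLE,FALSE
caution,Malignancy (excluding BCC),MG02.,READ,YEARS_BEFORE,5,POSSIBLE,FALSE
caution,Malignancy (excluding BCC),Z09.9,ICD10,YEARS_BEFORE,5,POSSIBLE,FALSE
caution,Myasthenia gravis,MA01.,READ,ANY_BEFORE,,POSSIBLE,FALSE
caution,Myasthenia gravis,MA02.,READ,ANY_BEFORE,,POSSIBLE,FALSE
caution,Myasthenia gravis,Z10.0,ICD10,ANY_BEFORE,,POSSIBLE,FALSE
caution,Myocardial infarction,MI01.,READ,MONTHS_BEFORE,6,WITH_CAUTION,FALSE
caution,Myocardial infarction,MI02.,READ,MONTHS_BEFORE,6,WITH_CAUTION,FALSE
caution,Myocardial infarction,MIHX.,READ,MONTHS_BEFORE,6,WITH_CAUTION,TRUE
caution,Myocardial infarction,Z11.1,ICD10,MONTHS_BEFORE,6,WITH_CAUTION,FALSE
caution,Myopathy,MY01.,READ,ANY_BEFORE,,WITH_CAUTION,FALSE
caution,Myopathy,MY02.,READ,ANY_BEFORE,,WITH_CAUTION,FALSE
caution,Myopathy,Z12.2,ICD10,ANY_BEFORE,,WITH_CAUTION,FALSE
caution,Ocular herpes simplex,OH01.,READ,ANY_BEFORE,,UNLIKELY,FALSE
caution,Ocular herpes simplex,OH02.,READ,ANY_BEFORE,,UNLIKELY,FALSE
caution,Ocular herpes simplex,Z13.3,ICD10,ANY_BEFORE,,UNLIKELY,FALSE
caution,Osteoporosis,OP01.,READ,ANY_BEFORE,,WITH_CAUTION,FALSE
caution,Osteoporosis,OP02.,READ,ANY_BEFORE,,WITH_CAUTION,FALSE
caution,Osteoporosis,Z14.4,ICD10,ANY_BEFORE,,WITH_CAUTION,FALSE
caution,Peptic ulcer,PU01.,READ,YEARS_BEFORE,1,WITH_CAUTION,FALSE
caution,Peptic ulcer,PU02.,READ,YEARS_BEFORE,1,WITH_CAUTION,FALSE
caution,Peptic ulcer,Z15.5,ICD10,YEARS_BEFORE,1,WITH_CAUTION,FALSE
caution,Septicaemia/sepsis,SE01.,READ,MONTHS_BEFORE,3,UNLIKELY,FALSE
caution,Septicaemia/sepsis,SE02.,READ,MONTHS_BEFORE,3,UNLIKELY,FALSE
caution,Septicaemia/sepsis,SEHX.,READ,MONTHS_BEFORE,3,UNLIKELY,TRUE
caution,Septicaemia/sepsis,Z16.6,ICD10,MONTHS_BEFORE,3,UNLIKELY,FALSE
caution,Severe mental illness,SM01.,READ,YEARS_BEFORE,10,WITH_CAUTION,FALSE
caution,Severe mental illness,SM02.,READ,YEARS_BEFORE,10,WITH_CAUTION,FALSE
caution,Severe mental illness,Z17.7,ICD10,YEARS_BEFORE,10,WITH_CAUTION,FALSE
caution,Systemic sclerosis,SS01.,READ,ANY_BEFORE,,POSSIBLE,FALSE
caution,Systemic sclerosis,SS02.,READ,ANY_BEFORE,,POSSIBLE,FALSE
caution,Systemic sclerosis,Z18.8,ICD10,ANY_BEFORE,,POSSIBLE,FALSE
caution,Tuberculosis,TB01.,READ,ANY_BEFORE,,UNLIKELY,FALSE
caution,Tuberculosis,TB02.,READ,ANY_BEFORE,,UNLIKELY,FALSE
caution,Tuberculosis,Z20.0,ICD10,ANY_BEFORE,,UNLIKELY,FALSE
caution,Ulcerative colitis,UC01.,READ,YEARS_BEFORE,5,POSSIBLE,FALSE
caution,Ulcerative colitis,UC02.,READ,YEARS_BEFORE,5,POSSIBLE,FALSE
caution,Ulcerative colitis,Z21.1,ICD10,YEARS_BEFORE,5,POSSIBLE,FALSE
caution,Varicella zoster vaccine,VZ01.,READ,MONTHS_BEFORE,3,WITH_CAUTION,FALSE
caution,Varicella zoster vaccine,VZ02.,READ,MONTHS_BEFORE,3,WITH_CAUTION,FALSE
caution,Varicella zoster vaccine,VZVAX1,PRODUCT,MONTHS_BEFORE,3,WITH_CAUTION,FALSE
caution,Varicella zoster vaccine,VZVAX2,PRODUCT,MONTHS_BEFORE,3,WITH_CAUTION,FALSE
caution,Varicella zoster vaccine,Z22.2,ICD10,MONTHS_BEFORE,3,WITH_CAUTION,FALSE
caution,Venous thromboembolic disorders,VT01.,READ,ANY_BEFORE,,POSSIBLE,FALSE
caution,Venous thromboembolic disorders,VT02.,READ,ANY_BEFORE,,POSSIBLE,FALSE
caution,Venous thromboembolic disorders,Z19.9,ICD10,ANY_BEFORE,,POSSIBLE,FALSE
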