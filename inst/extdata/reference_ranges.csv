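abbreviation,name,sample_type,lower,upper,unit
AFP,alpha-fetoprotein,Serum,0,7,ng/ml
AG,anion gap,Serum,8,30,mmol/l
ALB,albumin,Serum,35,55,g/l
ALP,alkaline phosphatase,Serum,25,130,u/l
ALT,alanine aminotransferase,Serum,1,45,u/l
AST,aspartate aminotransferase,Serum,6,40,u/l
BASO#,basophil cell count,full blood,0,0.06,10^9/L
BASO%,basophil cell ratio,full blood,0,1,%
BUN,blood urea nitrogen,Serum,1.7,8.3,mmol/l
Ca,calcium,Serum,1.12,1.32,mmol/l
CA125,carbohydrate antigen 125,Serum,0,35,U/ml
CA19-9,carbohydrate antigen 19-9,Serum,0,37,U/ml
CEA,carcinoembryonic antigen,Serum,0,5,ng/ml
CL,chlorine,Serum,99,110,mmol/l
CO2CP,carbon dioxide combining power,Serum,18,30,mmol/l
CREA,creatinine,Serum,44,144,umol/l
DBIL,direct bilirubin,Serum,1.5,7,umol/l
EO#,eosinophil count,full blood,0.02,0.52,10^9/L
EO%,eosinophil ratio,full blood,0.02,0.52,10^9/L
GGT,gamma glutamyltransferase,Serum,3,73,u/l
GLO,globulin,Serum,20,40,g/l
GLU.,glucose,Serum,3.9,6.1,mmol/l
HCT,hematocrit,full blood,0.35,0.45,L/L
HE4,human epididymis protein 4,Serum,0,140,pmol/L
HGB,hemoglobin,full blood,110,150,g/l
IBIL,indirect bilirubin,Serum,2,15,umol/L
K,kalium,Serum,3.5,5.3,mmol/l
LYM#,lymphocyte count,full blood,1.1,3.2,10^9/L
LYM%,lymphocyte ratio,full blood,20,50,%
MCH,mean corpuscular hemoglobin,full blood,27,34,pg
MCV,mean corpuscular volume,full blood,82,100,fL
Mg,magnesium,Serum,0.73,1.3,mmol/l
MONO#,mononuclear cell count,full blood,0.1,0.6,10^9/L
MONO%,monocyte ratio,full blood,3,10,%
MPV,mean platelet volume,full blood,7.4,12.5,fL
Na,natrium,Serum,137,147,mmol/l
NEU,neutrophil ratio,full blood,40,75,%
PCT,thrombocytocrit,full blood,0.114,0.282,L/L
PDW,platelet distribution width,full blood,15.5,18.1,%
PHOS,phosphorus,Serum,0.7,1.62,mmol/l
PLT,platelet count,full blood,125,350,10^9/L
RBC,red blood cell count,full blood,3.5,5.5,10^12/L
RDW,red blood cell distribution width,full blood,10.6,15.5,%
TBIL,total bilirubin,Serum,4,19,umol/l
TP,total protein,Serum,60,82,g/l
UA,uric acid,Serum,90,450,umol/l
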