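CC(=O)Oc1ccccc1C(=O)O aspirin
CC(C)Cc1ccc(cc1)C(C)C(=O)O ibuprofen
CC(=O)Nc1ccc(O)cc1 paracetamol
Cn1cnc2c1c(=O)n(C)c(=O)n2C caffeine
CN1C2CCC1CC(C2)OC(=O)C(CO)c1ccccc1 atropine
Clc1ccccc1C2=NCC(=O)Nc3ccc(cc23)[N+](=O)[O-] clonazepam_like
CC(N)Cc1ccccc1 amphetamine
CNC(C)Cc1ccccc1 methamphetamine
NCCc1ccc(O)c(O)c1 dopamine
NC(Cc1ccc(O)c(O)c1)C(=O)O dopa
C(Cc1ccccc1)NC levomethamphetamine_like
OC(=O)c1ccccc1O salicylic_acid
OC(=O)c1ccccc1 benzoic_acid
Nc1ccc(cc1)C(=O)O paba
NC(=O)c1ccccc1 benzamide
c1ccc2[nH]ccc2c1 indole
NC(Cc1c[nH]c2ccccc12)C(=O)O tryptophan
NCCc1c[nH]c2ccccc12 tryptamine
CN(C)CCc1c[nH]c2ccccc12 dmt
OCC(N)Cc1ccccc1 phenylalaninol
NC(Cc1ccccc1)C(=O)O phenylalanine
NC(Cc1ccc(O)cc1)C(=O)O tyrosine
NC(CO)C(=O)O serine
NC(CS)C(=O)O cysteine
NC(CC(=O)O)C(=O)O aspartate
NC(CCC(=O)O)C(=O)O glutamate
NC(C)C(=O)O alanine
NC(C(C)C)C(=O)O valine
NC(CC(C)C)C(=O)O leucine
NC(CCCNC(=N)N)C(=O)O arginine
NC(CCCCN)C(=O)O lysine
OC(=O)CCC(=O)O succinic_acid
OC(=O)C=CC(=O)O fumaric_acid
OC(C(=O)O)C(O)C(=O)O tartaric_acid
OC(=O)CC(O)(CC(=O)O)C(=O)O citric_acid
CC(O)C(=O)O lactic_acid
CCO ethanol
CC(C)O isopropanol
OCCO ethylene_glycol
OCC(O)CO glycerol
CCOC(=O)C ethyl_acetate
CC(=O)C acetone
CCN(CC)CC triethylamine
c1ccncc1 pyridine
c1ccc2ncccc2c1 quinoline
c1ccc2c(c1)cccn2 isoquinoline_like
c1cnc2[nH]ccc2c1 azaindole
c1ccc2c(c1)oc1ccccc12 dibenzofuran
c1ccc2c(c1)sc1ccccc12 dibenzothiophene
c1ccc2c(c1)[nH]c1ccccc12 carbazole
c1ccc(-c2ccccc2)cc1 biphenyl
c1ccc(Cc2ccccc2)cc1 diphenylmethane
c1ccc(Oc2ccccc2)cc1 diphenyl_ether
Oc1ccccc1 phenol
Oc1ccc(O)cc1 hydroquinone
Nc1ccccc1 aniline
CN(C)c1ccccc1 dimethylaniline
COc1ccccc1 anisole
Cc1ccccc1 toluene
Cc1ccccc1C xylene
Clc1ccccc1 chlorobenzene
Clc1ccc(Cl)cc1 dichlorobenzene
Fc1ccccc1 fluorobenzene
FC(F)(F)c1ccccc1 benzotrifluoride
N#Cc1ccccc1 benzonitrile
O=[N+]([O-])c1ccccc1 nitrobenzene
O=Cc1ccccc1 benzaldehyde
CC(=O)c1ccccc1 acetophenone
OCc1ccccc1 benzyl_alcohol
NCc1ccccc1 benzylamine
O=C(O)c1ccc(Cl)cc1 chlorobenzoic_acid
CCOC(=O)c1ccccc1 ethyl_benzoate
O=S(=O)(N)c1ccccc1 benzenesulfonamide
NS(=O)(=O)c1ccc(N)cc1 sulfanilamide
CC1CCCCC1 methylcyclohexane
C1CCCCC1 cyclohexane
C1CCNCC1 piperidine
C1CNCCN1 piperazine
C1COCCN1 morpholine
C1CCNC1 pyrrolidine
C1CCOC1 thf
O1CCOCC1 dioxane
CN1CCN(CC1)c1ccccc1 phenylpiperazine
CN1CCC(CC1)O methylpiperidinol
OC1CCCCC1 cyclohexanol
O=C1CCCCC1 cyclohexanone
O=C1CCCN1 pyrrolidinone
CN1CCCC1=O nmp
O=C1NC(=O)NC(=O)C1 barbituric_acid
CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(=O)O penicillin_g
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1 salbutamol
CNCC(O)c1ccc(O)c(O)c1 adrenaline
NCC(O)c1ccc(O)c(O)c1 noradrenaline
COc1cc2c(cc1OC)CCN(C)C2 dimethoxy_thq
CN1CCc2cccc3c2C1Cc1ccc(O)c(O)c13 apomorphine_like
CCN(CC)C(=O)c1ccccc1 diethylbenzamide
CCN(CC)CCNC(=O)c1ccc(N)cc1 procainamide
CCN(CC)CCOC(=O)c1ccc(N)cc1 procaine
COC(=O)c1ccccc1N methyl_anthranilate
Cc1ccc(cc1)S(=O)(=O)N tosylamide
Cc1ccc(cc1)S(=O)(=O)O tosylic_acid
OCC1OC(O)C(O)C(O)C1O glucose
OCC1OC(OC2C(O)C(O)C(O)OC2CO)C(O)C(O)C1O disaccharide
CC(=O)NC1C(O)OC(CO)C(O)C1O glucosamine_acetyl
Nc1ncnc2[nH]cnc12 adenine
O=c1[nH]cnc2[nH]cnc12 hypoxanthine
Nc1nc2[nH]cnc2c(=O)[nH]1 guanine
Cc1cn(C)c(=O)[nH]c1=O methylthymine
O=c1cc[nH]c(=O)[nH]1 uracil
Nc1cc[nH]c(=O)n1 cytosine
OC1CC(OC1CO)n1ccc(N)nc1=O deoxycytidine_like
CN1CCC23c4c5ccc(O)c4OC2C(O)C=CC3C1C5 morphine
COc1ccc2c(c1)c(CC(=O)O)c(C)n2C(=O)c1ccc(Cl)cc1 indomethacin
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1 atenolol
CC(C)NCC(O)COc1cccc2ccccc12 propranolol
CCOc1ccccc1OCCNC(C)C viloxazine_like
COc1ccc(CCN(C)C)cc1 methoxyphenethylamine
CN(C)CCCN1c2ccccc2CCc2ccccc21 imipramine
CN(C)CCC=C1c2ccccc2CCc2ccccc21 amitriptyline
Clc1ccc2c(c1)C(c1ccccc1)=NCC(=O)N2 nordazepam_like
OC(c1ccccc1)(c1ccccc1)C1CCNCC1 pipradrol_like
Clc1ccccc1-c1nc2ccccc2[nH]1 chlorophenyl_benzimidazole
c1ccc(-c2nc3ccccc3[nH]2)cc1 phenylbenzimidazole
CC(=O)OCC(=O)C1(O)CCC2C3CCC4=CC(=O)CCC4(C)C3C(O)CC21C cortisone_like
CC12CCC3c4ccc(O)cc4CCC3C1CCC2O estradiol
CC(C)=CCCC(C)=CCO geraniol
CC1=CCC(CC1)C(C)(C)O terpineol
CC(C)C1CCC(C)CC1O menthol
CC1(C)C2CCC1(C)C(=O)C2 camphor
C1CC2CCC1C2 norbornane
C1C2CC3CC1CC(C2)C3 adamantane
NC1(CC(=O)O)CCCCC1 gabapentin_like
NCC1(CC(=O)O)CCCCC1 gabapentin
CN(C)C(=N)NC(=N)N metformin
NC(=O)NC(=O)N biuret
NC(N)=O urea
CNC(=O)Oc1cccc2ccccc12 carbaryl
CCOP(=S)(OCC)Oc1ccc([N+](=O)[O-])cc1 parathion
COP(=O)(OC)OC=C(Cl)Cl dichlorvos
ClC(Cl)=C(c1ccc(Cl)cc1)c1ccc(Cl)cc1 dde
Oc1ccc(Cl)cc1Cc1cc(Cl)ccc1O dichlorophene
CC(C)(c1ccc(O)cc1)c1ccc(O)cc1 bisphenol_a
OCCN1CCN(CCCN2c3ccccc3Sc3ccc(Cl)cc32)CC1 perphenazine_like
CN1CCN(CCCN2c3ccccc3Sc3ccc(Cl)cc32)CC1 prochlorperazine
CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21 chlorpromazine
NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O hydrochlorothiazide
CC(O)(CC(=O)O)c1ccccc1 phenyl_hydroxybutyrate
CC(Cc1ccc(O)cc1)NCCc1ccc(O)cc1 ractopamine_like
COc1cc(CC(C)N)cc(OC)c1OC trimethoxyamphetamine
CCC(C)C(=O)OC1CC(C)C=C2C=CC(C)C(CCC3CC(O)CC(=O)O3)C21 lovastatin_like
CC(C)(C)c1ccc(O)cc1 butylphenol
CC(C)(C)c1cc(C(C)(C)C)c(O)c(C(C)(C)C)c1 bht_like
CCCCCCCCCCCCCCCC(=O)O palmitic_acid
CCCCCCCCC=CCCCCCCCC(=O)O oleic_acid
CCCCCC=CCC=CCCCCCCCC(=O)O linoleic_acid
OC(=O)CCCCCCCCCCCCCCCCC(=O)O octadecanedioic_acid
CCCCCCCCCCCCOS(=O)(=O)O dodecyl_sulfate
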