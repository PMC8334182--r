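"2,4-D"
Aflatoxin M1,AFM1
Amoxicillin
Ampicillin
Atrazine
Bacitracin
Cefoperazone
Cefquinome
Ceftiofur,Ceftiofur sodium
Cephalexin
Cephapirin,Cephapirin sodium
Clindamycin
Cloxacillin
Chloramphenicol,Chloramphenicol D
Chlortetracycline
Danofloxacin
Dapsone
Dicloxacillin
Dihydrostreptomycin
Enrofloxacin
Erythromycin
Florfenicol
Flunixin,Flunixin meglumine
Gentamicin,Gentamicin sulfate
Hetacillin
Kanamycin
Lincomycin
Neomycin
Novobiocin
Oxacillin
Oxytetracycline
Penicillin,Penicillin G,Benzylpenicillin,benzylpenicillin procaine,benzathine penicillin
Pirlimycin
Polymixin B
Rifaximin
Spectinomycin
Streptomycin
Sulfachlorpyridazine
Sulfadiazine
Sulfadimethoxine
Sulfadoxine
Sulfaethosxypyridazine
Sulfamerazine
Sulfamethazine
Sulfamethizole
Sulfamethoxazole
Sulfanilamide
Sulfapyridine
Sulfaquinoxaline
Sulfathiazole
Tetracycline,Tetracycline hydrochloride
Thiamphenicol
Tilmicosin
Trimethoprim
Tulathromycin
Tylosin
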