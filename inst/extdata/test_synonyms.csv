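2,4-D RaPID Assay
Atrazine RaPID Assay
Benomyl RaPID Assay
BetaStar Advanced for Beta-Lactams
BetaStar Advanced for Tetracycline
Beta Star 4D
"BetaStar 4D Beta-Lactam, Tetracycline, Streptomycin, Chloramphenicol"
BetaStar S for Sulfonamides
BetaStar for Quinolone
Charm II Aflatoxin
Charm II Amphenicol
Charm II Beta-Lactam
Charm II Chloramphenicol
Charm II Cloxacillin
Charm II Gentamicin and Neomycin
Charm II Gentamicin and Streptomycin
Charm II Macrolide
Charm II Novobiocin
Charm II Streptomycin
Charm II Sulfonamide
Charm II Tetracycline
Charm 3 SL3 Beta-Lactam
Charm B. stearothermophilus Tablet Disc Assay
Charm Beta-Lactam 30 s
Charm Blue Yellow II
Charm Cowside II
Charm Enroflox
Charm Flunixin and Beta-Lactam
Charm Gentamicin
Charm HPLC Receptogram
Charm KIS,Charm Kidney Inhibition Swab,KIS
Charm MRL Beta-Lactam
Charm MRL Beta-Lactam 1-min
Charm MRL Beta-Lactam 3-min
Charm MRL Beta-Lactam and Tetracycline 2-min
Charm MRL Beta-Lactam and Tetracycline
Charm MRL Beta-Lactam and RF Tetracycline 2-min
Charm Quad
Charm Quad 1
Charm Quad 2
Charm Quad 3
Charm Quinolone
Charm ROSA Amphenicol
Charm ROSA Chloramphenicol
Charm ROSA MRL Aflatoxin
Charm ROSA SL Aflatoxin
Charm ROSA Macrolide
Charm ROSA Neomycin and Streptomycin
Charm ROSA Pirlimycin
Charm ROSA Streptomycin
Charm ROSA Sulfa
Charm ROSA Tetracycline
Charm SL Beta-Lactam,Charm SL,CharmSL
Charm Streptomycin
Charm Tetracycline
Charm TRIO
Delvotest BLF
Delvotest P 5 Pack
Delvotest P/ Delvotest P Mini,Delvotest P,Delvotest P Mini
Delvotest SP-NT
Delvotest T
Eclipse 3G
Meatsafe B-Lactam
Meatsafe Gentamicin Strip
Penzyme Milk Test
PremiTest
Reveal for Aflatoxin M1
SNAP Aflatoxin M1,SNAP AFM1
SNAP Beta-Lactam ST
SNAP Beta-Lactam ST Plus
SNAP Duo ST Plus,SNAPduo ST Plus
SNAP Gentamicin
SNAP NBL,New Snap Beta-Lactam
SNAP Sulfamethazine
SNAP Tetracycline
SNAP TRIO Japan
Veratox for Enrofloxacin
Veratox for Florfenicol
Veratox for Fluoroquinolone
Veratox for Gentamicin
Veratox for Neomycin
Veratox for Oxytetracycline
Veratox for Sulfonamides
Veratox for Tetracycline
Veratox for Tylosin
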