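"Charm Sciences, Inc",Charm Sciences,Charm
"DSM Food Specialties USA, Inc",DSM Food Specialties,DSM
"IDEXX Laboratories, Inc",IDEXX Laboratories,IDEXX
Neogen Corporation,Neogen
Silver Lake Research Corporation,Silver Lake Research
"Strategic Diagnostics, Inc",Strategic Diagnostics
ZEU-Immunotec,ZEU Immunotec
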