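Buffalo
Camel
Cattle,Cow,Bovine,Dairy cow
Chicken,Poultry
Honeybees,Honeybee,Bees
Horse,Equine
Sheep,Ovine
Swine,Pig,Porcine
Turkey
Various fish/shellfish species,Fish,Shellfish
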