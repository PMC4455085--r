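compound,category,acetic_acid_extract,sulfuric_acid_treatment
Microcrystalline cellulose,excipient,Colorless,-
Croscarmellose,excipient,Colorless,Colorless
Fumarate,excipient,Colorless,Colorless
Talc,excipient,Colorless,Colorless
Lactose,excipient,Colorless,Colorless
Starch,excipient,Colorless,Colorless
SiO2,excipient,Colorless,Colorless
Mg stearate,excipient,Colorless,White precipitant
Dihydroartemisinin,artemisinin,Colorless,Orange/red
Artesunate,artemisinin,Colorless,Red
Artemether,artemisinin,Colorless,Orange/red
Artemisinin,artemisinin,Colorless,Yellow/orange
Sulfamethoxazole,antimicrobial,Colorless,Colorless
Acetaminophen,other,Colorless,Colorless
Aspirin,other,Colorless,Colorless
Pyrimethamine,antimalarial,Colorless,Colorless
Trimethoprim,antimicrobial,Colorless,Colorless
Chloroquine,antimalarial,Colorless,Colorless
Chloramphenicol,antimicrobial,Colorless,Colorless
Erythromycin,antimicrobial,Colorless,Black
Ciprofloxacin,antimicrobial,Colorless,Colorless
Primaquine,antimalarial,Yellow/orange,Weak yellow
Ampicillin,antimicrobial,Colorless,Colorless
Sulfadoxine,antimalarial,Colorless,Colorless
Tetracycline,antimicrobial,Yellow/orange,Orange
Mefloquine,antimalarial,Colorless,Colorless
Amoxicillin,antimicrobial,Colorless,Colorless
Piperaquine,antimalarial,Colorless,Colorless
Amodiaquine,antimalarial,Weak yellow,Weak yellow
Lumefantrine,antimalarial,Yellow,Yellow
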