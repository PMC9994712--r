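well,substrate,role
A1,Negative Control,no_carbon
A2,L-Arabinose,substrate
A3,N-Acetyl-D-Glucosamine,substrate
A4,D-Saccharic Acid,substrate
A5,Succinic Acid,substrate
A6,D-Galactose,substrate
A7,L-Aspartic Acid,substrate
A8,L-Proline,substrate
A9,D-Alanine,substrate
A10,D-Trehalose,substrate
A11,D-Mannose,substrate
A12,Dulcitol,substrate
B1,D-Serine,substrate
B2,D-Sorbitol,substrate
B3,Glycerol,substrate
B4,L-Fucose,substrate
B5,D-Glucuronic Acid,substrate
B6,D-Gluconic Acid,substrate
B7,D.L-a-Glycerol-Phosphate,substrate
B8,D-Xylose,substrate
B9,L-Lactic Acid,substrate
B10,Formic Acid,substrate
B11,D-Mannitol,substrate
B12,L-Glutamic Acid,substrate
C1,D-Glucose-6-Phosphate,substrate
C2,D-Galactonic Acid-g-Lactone,substrate
C3,D.L-Malic Acid,substrate
C4,D-Ribose,substrate
C5,Tween 20,substrate
C6,L-Rhamnose,substrate
C7,D-Fructose,substrate
C8,Acetic Acid,substrate
C9,a-D-Glucose,substrate
C10,Maltose,substrate
C11,D-Melibiose,substrate
C12,Thymidine,substrate
D1,L-Asparagine,substrate
D2,D-Aspartic Acid,substrate
D3,D-Glucosaminic Acid,substrate
D4,1.2-Propanediol,substrate
D5,Tween 40,substrate
D6,a-Keto-Glutaric Acid,substrate
D7,a-Keto-Butyric Acid,substrate
D8,a-Methyl-D-Galactoside,substrate
D9,a-D-Lactose,substrate
D10,Lactulose,substrate
D11,Sucrose,substrate
D12,Uridine,substrate
E1,L-Glutamine,substrate
E2,m-Tartaric Acid,substrate
E3,D-Glucose-1-Phosphate,substrate
E4,D-Fructose-6-Phosphate,substrate
E5,Tween 80,substrate
E6,a-Hydroxy-Glutaric Acid-g-Lactone,substrate
E7,a-Hydroxy-Butyric Acid,substrate
E8,b-Methyl-D-Glucoside,substrate
E9,Adonitol,substrate
E10,Maltotriose,substrate
E11,2-Deoxy-Adenosine,substrate
E12,Adenosine,substrate
F1,Glycyl-L-Aspartic Acid,substrate
F2,Citric Acid,substrate
F3,m-Inositol,substrate
F4,D-Threonine,substrate
F5,Fumaric Acid,substrate
F6,Bromo-Succinic Acid,substrate
F7,Propionic Acid,substrate
F8,Mucic Acid,substrate
F9,Glycolic Acid,substrate
F10,Glyoxylic Acid,substrate
F11,D-Cellobiose,substrate
F12,Inosine,substrate
G1,Glycyl-L-Glutamic Acid,substrate
G2,Tricarballylic Acid,substrate
G3,L-Serine,substrate
G4,L-Threonine,substrate
G5,L-Alanine,substrate
G6,L-Alanyl-Glycine,substrate
G7,Acetoacetic Acid,substrate
G8,N-Acetyl-b-D-Mannosamine,substrate
G9,Mono-Methyl Succinate,substrate
G10,Methyl Pyruvate,substrate
G11,D-Malic Acid,substrate
G12,L-Malic Acid,substrate
H1,Glycyl-L-Proline,substrate
H2,p-Hydroxy-Phenylacetic Acid,substrate
H3,m-Hydroxy-Phenylacetic Acid,substrate
H4,Tyramine,substrate
H5,D-Psicose,substrate
H6,L-Lyxose,substrate
H7,Glucuronamide,substrate
H8,Pyruvic Acid,substrate
H9,L-Galactonic Acid-g-Lactone,substrate
H10,D-Galacturonic Acid,substrate
H11,Phenylethylamine,substrate
H12,2-Aminoethanol,substrate
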