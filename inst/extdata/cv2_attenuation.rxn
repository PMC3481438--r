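# BMP / Cv-2 co-factor network, simplified with the free ligand clamped.
# Species: B Type I receptor, C BMP:receptor (signaling), D Cv-2,
# E BMP:Cv-2, Z BMP:receptor:Cv-2. Intermediate-complex kinetics use the
# strong symmetric rates of the noise-attenuating representative vector;
# the clamp level A sets ~12 bound receptors deterministically.
param k1  = 0.013282
param km1 = 0.01
param k2  = 0.013282
param km2 = 0.1
param k3  = 1.3282
param km3 = 0.01
param k4  = 1.3282
param km4 = 0.01
clamp A = 0.4
species B init 100
species C init 0
species D init 105
species E init 0
species Z init 0
reaction R1: A + B -> C @ k1
reaction R2: C -> A + B @ km1
reaction R3: A + D -> E @ k2
reaction R4: E -> A + D @ km2
reaction R5: B + E -> Z @ k3
reaction R6: Z -> B + E @ km3
reaction R7: C + D -> Z @ k4
reaction R8: Z -> C + D @ km4
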