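# Type II receptor recruitment, Case II: ligand (B) clamped, recruitment
# of the Type II receptor onto the bound BMP:Type I complex; BR1R2 signals.
param k1  = 0.013282
param km1 = 0.01
param k3  = 0.013282
param km3 = 0.0316227766016838
clamp B = 0.0147
species R1 init 100
species R2 init 100
species BR1 init 0
species BR1R2 init 0
reaction r1: B + R1 -> BR1 @ k1
reaction r2: BR1 -> B + R1 @ km1
reaction r5: BR1 + R2 -> BR1R2 @ k3
reaction r6: BR1R2 -> BR1 + R2 @ km3
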