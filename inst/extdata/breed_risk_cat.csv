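breed,risk_group
Burmese,high
Russian blue,high
Norwegian forest cat,high
European shorthair,high
Maine coon,low
Persian,low
British shorthair,low
Siberian,low
Birman,low
Ragdoll,low
Bengal,low
Domestic cat,moderate
Siamese,moderate
Ocicat,moderate
Devon rex,moderate
Cornish rex,moderate
Abyssinian,moderate
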