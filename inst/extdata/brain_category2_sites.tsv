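# Coding-region A-to-I editing sites with mean editing frequency between the
# 0.08% background error rate and 1% ("Category II") in the same normal
# human brain samples.
gene
AEBP1
KCNQ5
KIF1A
PTPRN2
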