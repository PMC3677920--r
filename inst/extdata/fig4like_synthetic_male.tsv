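# SYNTHETIC 29-taxon fixture (25 ingroup + 4 outgroup).
# Hand-built ultrametric topology with the published character census:
# two taxa with both sacs and barrier, one with neither, the rest S+B- or S-B+.
# The branching order is plausible but synthetic, not an estimated phylogeny.
taxon	state
out1	S+P-
out2	S+P-
out3	S+P-
out4	S+P-
nsA1	S-P+
nsA2	S-P+
nsA3	S-P+
nsA4	S-P+
nsA5	S-P+
sacE1	S+P-
sacE2	S+P-
sacE3	S+P-
sacE4	S+P-
nsB1	S-P+
nsB2	S-P+
nsB3	S-P+
nsB4	S-P+
sacF1	S+P-
sacF2	S+P-
nsC1	S-P-
nsC2	S-P-
nsC3	S-P-
sacG1	S+P-
sacG2	S+P-
hgrandis_like	S+P-
hnsp3_like	S+P-
hmac_like	S-P-
hnsp2_like	S-P-
relictum_like	S-P-
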