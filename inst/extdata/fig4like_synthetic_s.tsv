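# SYNTHETIC 29-taxon fixture (25 ingroup + 4 outgroup).
# Hand-built ultrametric topology with the published character census:
# two taxa with both sacs and barrier, one with neither, the rest S+B- or S-B+.
# The branching order is plausible but synthetic, not an estimated phylogeny.
taxon	state
out1	S+
out2	S+
out3	S+
out4	S+
nsA1	S-
nsA2	S-
nsA3	S-
nsA4	S-
nsA5	S-
sacE1	S+
sacE2	S+
sacE3	S+
sacE4	S+
nsB1	S-
nsB2	S-
nsB3	S-
nsB4	S-
sacF1	S+
sacF2	S+
nsC1	S-
nsC2	S-
nsC3	S-
sacG1	S+
sacG2	S+
hgrandis_like	S+
hnsp3_like	S+
hmac_like	S-
hnsp2_like	S-
relictum_like	S-
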