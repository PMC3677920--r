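# SYNTHETIC 29-taxon fixture (25 ingroup + 4 outgroup).
# Hand-built ultrametric topology with the published character census:
# two taxa with both sacs and barrier, one with neither, the rest S+B- or S-B+.
# The branching order is plausible but synthetic, not an estimated phylogeny.
taxon	state
out1	B-
out2	B-
out3	B-
out4	B-
nsA1	B+
nsA2	B+
nsA3	B+
nsA4	B+
nsA5	B+
sacE1	B-
sacE2	B-
sacE3	B-
sacE4	B-
nsB1	B+
nsB2	B+
nsB3	B+
nsB4	B+
sacF1	B-
sacF2	B-
nsC1	B+
nsC2	B+
nsC3	B+
sacG1	B-
sacG2	B-
hgrandis_like	B+
hnsp3_like	B+
hmac_like	B+
hnsp2_like	B+
relictum_like	B-
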