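# Published per-run log marginal-likelihood approximations (stabilized
# harmonic mean, 1000 bootstrap replicates) from four independent MCMC
# runs per trait-evolution model on the leiobunine harvestman dataset.
# Columns: model identifier, run number, run mean, run standard error.
model	run	mean	se
male_6rate	1	-29.497	0.059
male_6rate	2	-29.661	0.062
male_6rate	3	-29.54	0.047
male_6rate	4	-29.723	0.056
male_2rate	1	-30.967	0.048
male_2rate	2	-31	0.044
male_2rate	3	-30.952	0.037
male_2rate	4	-31.493	0.04
male_6rate_fixedroot	1	-30.168	0.047
male_6rate_fixedroot	2	-30.145	0.05
male_6rate_fixedroot	3	-30.088	0.047
male_6rate_fixedroot	4	-30.171	0.051
indep_4rate	1	-38.492	0.06
indep_4rate	2	-38.404	0.05
indep_4rate	3	-38.466	0.059
indep_4rate	4	-38.393	0.047
dep_8rate	1	-35.232	0.037
dep_8rate	2	-32.852	0.047
dep_8rate	3	-33.153	0.062
dep_8rate	4	-33.175	0.058
dep_7rate_noprec	1	-38.989	0.019
dep_7rate_noprec	2	-38.552	0.018
dep_7rate_noprec	3	-38.586	0.018
dep_7rate_noprec	4	-38.16	0.019
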