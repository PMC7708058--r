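# Published per-enzyme assay summaries: mutant colony frequency (MF) and
# mean mutations per sequenced mutant gene (m). er_detectable is the
# detectable-sites error-rate estimate where reported (mutations/base).
enzyme	mf	m	er_detectable
WT	8.43e-5	1.1	5e-6
Exo-	4.50e-4	1.1	4e-5
Exo-L903F	5.30e-3	2.4	7e-4
Taq	4.70e-4	1.0	.
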