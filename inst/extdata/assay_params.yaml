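# Experimentally determined assay constants.
P: 0.025            # probability a newly-synthesized-strand mutation is expressed
e: 0.61             # tetracycline/ampicillin plating efficiency
comparator_error_rates:
  taq_high: 2.85e-4 # supplier estimate, pH 8.8 buffer (mutations/base)
  taq_low: 4.3e-5   # lower published estimate (mutations/base)
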