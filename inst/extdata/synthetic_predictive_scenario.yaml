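# Synthetic example scenario for `gtbiomark simulate`.
# Shaped like a 657-patient 1:1 randomized trial with a binary marker of
# prevalence 0.24. The response probabilities below are illustrative
# placeholders, not values estimated from any real trial; edit them to
# match your own study before drawing conclusions.
mode: predictive
'n': 657
prevalence: 0.24
response_probs:
  p11: 0.65
  p10: 0.45
  p01: 0.5
  p00: 0.5
designs:
- RS-2
- RS-3
- GT-2
- GT-3
reps: 2000
seed: 20210319
assay:
  sensitivity: 1.0
  specificity: 1.0
treatment_prob: 0.5
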