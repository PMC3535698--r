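# Reference per-tool reporting rates p(s|y) estimated on a published
# miR-124 Ago2-IP benchmark, and the genome-wide prior p(y=1) estimated
# from the same data. tpr = p(s=1|y=1), fpr = p(s=1|y=0); fnr/tnr are the
# complements.
prior: 0.0133
rates:
- tool: TargetScan
  tpr: 0.4082
  fpr: 0.0877
  tnr: 0.9123
  fnr: 0.5918
- tool: miRanda
  tpr: 0.3371
  fpr: 0.0783
  tnr: 0.9217
  fnr: 0.6629
- tool: PicTar
  tpr: 0.1798
  fpr: 0.0390
  tnr: 0.9610
  fnr: 0.8202
- tool: mirTarget
  tpr: 0.2285
  fpr: 0.0302
  tnr: 0.9698
  fnr: 0.7715
- tool: PITA
  tpr: 0.7603
  fpr: 0.3942
  tnr: 0.6058
  fnr: 0.2397
- tool: Diana-microT
  tpr: 0.4045
  fpr: 0.1474
  tnr: 0.8526
  fnr: 0.5955
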