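id: s3_docetaxel_utility
description: >
  Early switchers in the ctDNA-guided arm keep the mean ARPI utility while
  on docetaxel, reflecting quality of life that does not drop as fast after
  an early, pre-progression switch.
flags:
  switcher_docetaxel_utility: mean_arpi
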