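id: s4_reallife_docetaxel
description: >
  Second-line docetaxel PFS/OS replaced in both arms by real-world
  post-ARPI data (synthetic stand-in medians for the Japanese real-life
  series) instead of the first-line trial data of the base case.
overrides:
  lines.docetaxel.pfs.median: 5.8
  lines.docetaxel.os.median: 17.0
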