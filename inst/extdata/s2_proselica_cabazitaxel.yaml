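id: s2_proselica_cabazitaxel
description: >
  Patients who switch to docetaxel after 4 weeks receive cabazitaxel with
  second-line-setting survival data (PROSELICA-like synthetic stand-in
  medians shipped as the cabazitaxel_proselica line) instead of the
  third-line-setting data of the base case.
flags:
  switcher_cabazitaxel_line: cabazitaxel_proselica
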