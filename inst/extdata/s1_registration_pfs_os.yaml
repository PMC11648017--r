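id: s1_registration_pfs_os
description: >
  Predicted-durable patients in the ctDNA-guided arm keep their drug's
  registration-trial PFS/OS instead of the durable-responder curves,
  removing the survival advantage of the guided arm.
flags:
  durable_uses_trial_curves: true
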