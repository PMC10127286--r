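rcds:
  I: IPTG
  R: ribose
  F: fucose
  E: cellobiose
  P: fructose
adrs:
  WT: O1
  YQR: Oyqr
  HQN: Ottg
  GKR: Ogac
  TAN: Oagg
  NAR: Otat
  QAR: Ocgc
  ERN: Oata
positions:
- PROXIMAL
- CORE
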