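# Model registry: maps model names to agent constructors. "HGF" is accepted
# as an alias of "hBL" (one model, two names).
.agent_registry <- list(
  "RB"    = new_rb,
  "Nash"  = new_nash,
  "WSLS"  = new_wsls,
  "RL"    = new_rl,
  "1-BSL" = new_bsl(1),
  "2-BSL" = new_bsl(2),
  "3-BSL" = new_bsl(3),
  "hBL"   = new_hbl,
  "1-Inf" = new_inf(1),
  "2-Inf" = new_inf(2),
  "0-ToM" = new_tom0,
  "1-ToM" = new_ktom(1),
  "2-ToM" = new_ktom(2),
  "3-ToM" = new_ktom(3)
)
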