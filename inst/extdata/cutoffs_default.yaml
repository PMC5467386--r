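# Default three-class decision intervals per feature method.
# direction is how the score moves with IFL severity; t_mild separates
# NIFL from IFL Level 1, t_severe separates IFL Level 1 from IFL Level 2.
fi:
  direction: decreasing
  t_mild: 0.175
  t_severe: 0.095
order1:
  direction: decreasing
  t_mild: 6.19
  t_severe: 4.54
order2:
  direction: increasing
  t_mild: 1.17
  t_severe: 1.96
order3:
  direction: increasing
  t_mild: 0.34
  t_severe: 1.02
w3:
  direction: increasing
  t_mild: 0.87
  t_severe: 2.7
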