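epsilon: 0.01
matrices:
  U2_donor:
    offset: -3
    positions:
    - A: 0.4
      C: 0.2
      G: 0.2
      T: 0.2
    - A: 0.7
      C: 0.1
      G: 0.1
      T: 0.1
    - A: 0.1
      C: 0.1
      G: 0.7
      T: 0.1
    - A: 0.03
      C: 0.03
      G: 0.91
      T: 0.03
    - A: 0.03
      C: 0.03
      G: 0.03
      T: 0.91
    - A: 0.7
      C: 0.1
      G: 0.1
      T: 0.1
    - A: 0.7
      C: 0.1
      G: 0.1
      T: 0.1
    - A: 0.1
      C: 0.1
      G: 0.7
      T: 0.1
    - A: 0.1
      C: 0.1
      G: 0.1
      T: 0.7
    - A: 0.2
      C: 0.2
      G: 0.2
      T: 0.4
    - A: 0.2
      C: 0.2
      G: 0.2
      T: 0.4
    - A: 0.2
      C: 0.2
      G: 0.2
      T: 0.4
    - A: 0.25
      C: 0.25
      G: 0.25
      T: 0.25
  U2_acceptor:
    offset: -14
    positions:
    - A: 0.1
      C: 0.35
      G: 0.1
      T: 0.45
    - A: 0.1
      C: 0.35
      G: 0.1
      T: 0.45
    - A: 0.1
      C: 0.35
      G: 0.1
      T: 0.45
    - A: 0.1
      C: 0.35
      G: 0.1
      T: 0.45
    - A: 0.1
      C: 0.35
      G: 0.1
      T: 0.45
    - A: 0.1
      C: 0.35
      G: 0.1
      T: 0.45
    - A: 0.1
      C: 0.35
      G: 0.1
      T: 0.45
    - A: 0.1
      C: 0.35
      G: 0.1
      T: 0.45
    - A: 0.1
      C: 0.35
      G: 0.1
      T: 0.45
    - A: 0.1
      C: 0.35
      G: 0.1
      T: 0.45
    - A: 0.1
      C: 0.35
      G: 0.1
      T: 0.45
    - A: 0.2
      C: 0.4
      G: 0.2
      T: 0.2
    - A: 0.91
      C: 0.03
      G: 0.03
      T: 0.03
    - A: 0.03
      C: 0.03
      G: 0.91
      T: 0.03
    - A: 0.1
      C: 0.1
      G: 0.7
      T: 0.1
    - A: 0.25
      C: 0.25
      G: 0.25
      T: 0.25
    - A: 0.25
      C: 0.25
      G: 0.25
      T: 0.25
  U12_donor:
    offset: -3
    positions:
    - A: 0.25
      C: 0.25
      G: 0.25
      T: 0.25
    - A: 0.25
      C: 0.25
      G: 0.25
      T: 0.25
    - A: 0.25
      C: 0.25
      G: 0.25
      T: 0.25
    - A: 0.45
      C: 0.05
      G: 0.45
      T: 0.05
    - A: 0.03
      C: 0.03
      G: 0.03
      T: 0.91
    - A: 0.91
      C: 0.03
      G: 0.03
      T: 0.03
    - A: 0.03
      C: 0.03
      G: 0.03
      T: 0.91
    - A: 0.03
      C: 0.91
      G: 0.03
      T: 0.03
    - A: 0.03
      C: 0.91
      G: 0.03
      T: 0.03
    - A: 0.1
      C: 0.1
      G: 0.1
      T: 0.7
    - A: 0.1
      C: 0.1
      G: 0.1
      T: 0.7
    - A: 0.25
      C: 0.25
      G: 0.25
      T: 0.25
    - A: 0.25
      C: 0.25
      G: 0.25
      T: 0.25
  U12_branch:
    offset: 0
    positions:
    - A: 0.03
      C: 0.03
      G: 0.03
      T: 0.91
    - A: 0.03
      C: 0.03
      G: 0.03
      T: 0.91
    - A: 0.03
      C: 0.91
      G: 0.03
      T: 0.03
    - A: 0.03
      C: 0.91
      G: 0.03
      T: 0.03
    - A: 0.03
      C: 0.03
      G: 0.03
      T: 0.91
    - A: 0.03
      C: 0.03
      G: 0.03
      T: 0.91
    - A: 0.7
      C: 0.1
      G: 0.1
      T: 0.1
    - A: 0.7
      C: 0.1
      G: 0.1
      T: 0.1
    - A: 0.03
      C: 0.91
      G: 0.03
      T: 0.03
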