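- 'n': 49.0
  proc: RA
  trend: no
  p0: 0.2
  pTop: 0.8
- 'n': 49.0
  proc: RA
  trend: yes
  p0: 0.2
  pTop: 0.8
- 'n': 49.0
  proc: PBD
  trend: no
  p0: 0.2
  pTop: 0.8
- 'n': 49.0
  proc: PBD
  trend: yes
  p0: 0.2
  pTop: 0.8
- 'n': 98.0
  proc: RA
  trend: no
  p0: 0.2
  pTop: 0.61
- 'n': 98.0
  proc: RA
  trend: yes
  p0: 0.2
  pTop: 0.61
- 'n': 98.0
  proc: PBD
  trend: no
  p0: 0.2
  pTop: 0.61
- 'n': 98.0
  proc: PBD
  trend: yes
  p0: 0.2
  pTop: 0.61
- 'n': 490.0
  proc: RA
  trend: no
  p0: 0.2
  pTop: 0.364
- 'n': 490.0
  proc: RA
  trend: yes
  p0: 0.2
  pTop: 0.364
- 'n': 490.0
  proc: PBD
  trend: no
  p0: 0.2
  pTop: 0.364
- 'n': 490.0
  proc: PBD
  trend: yes
  p0: 0.2
  pTop: 0.364
- 'n': 490.0
  proc: CR
  trend: no
  p0: 0.2
  pTop: 0.364
- 'n': 490.0
  proc: CR
  trend: yes
  p0: 0.2
  pTop: 0.364
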