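# Reference nonlocal SIR experiment: periodic unit interval, triangular
# kernel w(x,y) = 0.3 * (0.2 - d(x,y))_+, removal rate 0.1, explicit Euler.
model: sir
level: monokinetic
grid:
  n: 100
  periodic: true
kernel:
  form: triangular
  amplitude: 0.3
  cutoff: 0.2
params:
  beta: 0.1
initial:
  v0:
    peak_center: 0.5
    peak_height: 0.05
    peak_width: 0.02
integrator:
  scheme: euler
  dt: 0.01
  t_end: 5.0
  output_times: [1.0, 2.0, 3.0, 4.0, 5.0]
seed: 1
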