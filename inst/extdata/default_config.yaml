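# Default run configuration for the standing-balance simulator.
# Every value shown equals the built-in default; edit and pass to
# read_balance_config() or the balance-sim.R command line.
anthropometry:
  gravity: 9.81
  foot_height: 0.1
  segments:
    foot:       {mass: 1.3, length: 0.3}
    lower_body: {mass: 35, length: 1.0}
    upper_body: {mass: 25, length: 0.6}
    right_arm:  {mass: 4, length: 0.6}
    left_arm:   {mass: 4, length: 0.6}
arm_mode: active
controller:
  dt: 0.035
  horizon: 29
  q_angle: [700000, 700000, 7000]
  q_vel: [70000, 70000, 700]
  r_scale: 1
  qf_factor: 100
  push_preview: false
protocol:
  force: 70
  push_duration: 1
  max_sim_time: 4
recovery:
  angle_tol: 0.01
  vel_tol: 0.02
  dwell: 0.5
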