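# Default instrument description; values mirror the physical system.
instrument:
  array:
    arc_radius: 65        # mm
    n_elements: 96
    element_width: 1.3    # mm
    element_height: 1.3   # mm
    inter_element_gap: 0.1
    center_frequency: 6   # MHz
    fractional_bandwidth: 0.55
  acquisition:
    sampling_rate: 40     # MHz
    samples_per_channel: 4096
    gain_db: 46
    prf: 10               # Hz
    hardware_lowpass: 10  # MHz
  camera:
    fov: [40, 40]         # mm
    pixels: [2048, 2040]
    exposure: 25          # ms
    read_noise: 2.5       # electrons RMS
    quantum_efficiency: 0.45
  medium:
    temperature: 25       # degC
scan:
  schedule:
    speed: 10             # deg/s
    sweep: 360            # deg
    prf: 10               # Hz
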