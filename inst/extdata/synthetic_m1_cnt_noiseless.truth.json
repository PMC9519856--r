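{"model":"M1","params":{"k_gl":0.0974,"k_aa":0.0247},"note":"synthetic fixture generated by make_known_parameter_dataset(); not experimental data"}
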