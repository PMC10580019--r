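# Shared fixtures: the reference plant/controller and one nominal run reused
# across test files. Everything is generated in code.

ref_plant <- tumour_model()                 # a = 0.27, b = 0.0074, c = log(2)/3.9
ref_ctrl <- backstepping_controller(k = 60)
u_inf <- steady_state_injection(ref_ctrl)   # k * c_nominal

nominal_run <- simulate_therapy(plant = ref_plant, controller = ref_ctrl,
                                sim = sim_config(t_end = 100))

ref_constants <- stability_constants(ref_ctrl, ref_plant, x0 = 1e4, y0 = 0)
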