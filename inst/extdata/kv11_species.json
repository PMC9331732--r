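{
  "comment": "Generative parameter sets for homomeric Kv1.1 wild-type, homomeric P403A and the 1:1 heteromeric population, as measured in HEK 293 cells. Voltages mV; activation/deactivation time constants ms; inactivation/recovery time constants s. k_tau slopes and frac_fast are generator defaults (not measured quantities); amplitude_20mV is the whole-cell current amplitude at +20 mV in display units used to calibrate g_max; tail_V is the tail-potential convention for the species.",
  "species": [
    {
      "name": "WT",
      "activation": { "V_half": -21.5, "k": 10.0 },
      "act_tau": { "tau_at_Vhalf": 9.4, "k_tau": -40.0 },
      "deact_tau": { "tau_at_Vhalf": 41.5, "k_tau": 25.0 },
      "inact": { "tau_fast": 4.9, "tau_slow": 37.4, "frac_fast": 0.3,
                 "tau_recovery": 3.4 },
      "amplitude_20mV": 2.1,
      "tail_V": -50
    },
    {
      "name": "P403A",
      "activation": { "V_half": 7.8, "k": 9.0 },
      "act_tau": { "tau_at_Vhalf": 31.7, "k_tau": -40.0 },
      "deact_tau": { "tau_at_Vhalf": 47.2, "k_tau": 25.0 },
      "inact": { "tau_fast": 5.8, "tau_slow": 42.1, "frac_fast": 0.3,
                 "tau_recovery": 2.2 },
      "amplitude_20mV": 0.4,
      "tail_V": -30
    },
    {
      "name": "WT+P403A",
      "activation": { "V_half": -4.3, "k": 12.0 },
      "act_tau": { "tau_at_Vhalf": 14.7, "k_tau": -40.0 },
      "deact_tau": { "tau_at_Vhalf": 41.5, "k_tau": 25.0 },
      "inact": { "tau_fast": 5.8, "tau_slow": 40.2, "frac_fast": 0.3,
                 "tau_recovery": 2.8 },
      "amplitude_20mV": 0.55,
      "tail_V": -30
    }
  ]
}
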