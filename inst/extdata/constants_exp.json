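{"k1":0.0015583,"k2":0.027332,"k3":7.0946e-07,"k4":1.3909e-05,"k5":3.3791e-05,"k6":0.05817,"k7":8.068e-05,"k8":1.1173e-05,"k9":0.0016387,"k10":3.9706e-06,"k11":0.00097736,"k12":0.17751,"k13":0.0001211,"k14":0.10304,"k15":1.0953e-05}
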