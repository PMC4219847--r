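{"k1":0.0010063,"k2":0.01313,"k3":3.5892e-07,"k4":5.829e-05,"k5":0.00088645,"k6":0.021387,"k7":6.1787e-05,"k8":1.2312e-05,"k9":0.0010528,"k10":2.1974e-05,"k11":0.00058482,"k12":0.10246,"k13":7.1993e-05,"k14":0.046617,"k15":6.6738e-05}
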