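{"k1":0.0013178,"k2":0.016753,"k3":4.1913e-07,"k4":4.379e-05,"k5":1.1091e-06,"k6":0.03921,"k7":5.9673e-05,"k8":1.1618e-05,"k9":0.0016991,"k10":1.1079e-06,"k11":0.00075142,"k12":0.057494,"k13":8.3475e-05,"k14":0.078662,"k15":4.4724e-06}
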