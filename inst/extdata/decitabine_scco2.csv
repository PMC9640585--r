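pressure_bar,temperature_K,solubility_molefrac
120,308,5.04e-05
120,318,4.51e-05
120,328,3.69e-05
120,338,2.84e-05
160,308,8.23e-05
160,318,9.37e-05
160,328,9.11e-05
160,338,7.79e-05
200,308,1.18e-04
200,318,1.55e-04
200,328,1.77e-04
200,338,2.05e-04
240,308,1.37e-04
240,318,1.87e-04
240,328,2.82e-04
240,338,3.71e-04
280,308,1.76e-04
280,318,2.40e-04
280,328,3.42e-04
280,338,4.90e-04
320,308,1.97e-04
320,318,2.69e-04
320,328,4.27e-04
320,338,7.15e-04
360,308,2.18e-04
360,318,3.40e-04
360,328,5.60e-04
360,338,8.74e-04
400,308,2.83e-04
400,318,5.06e-04
400,328,7.88e-04
400,338,1.07e-03
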