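class,precision,recall,f1
AlcoholBar,0.688,0.659,0.673
AlcoholStore,0.968,0.928,0.947
Convenience,0.762,0.823,0.791
Discount,0.89,0.807,0.846
FastFood,0.757,0.702,0.729
Grocery,0.616,0.439,0.513
Restaurant,0.618,0.683,0.649
JuiceCoffee,0.836,0.419,0.559
SpecialtyFoods,0.767,0.558,0.646
SweetsDesserts,0.867,0.643,0.738
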