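name,class,raw_score,boolean
Oak and Steel,AlcoholBar,0.688,TRUE
Oak and Steel,AlcoholStore,0.406,FALSE
Oak and Steel,Convenience,0.057,FALSE
Oak and Steel,Discount,0.023,FALSE
Oak and Steel,FastFood,0.025,FALSE
Oak and Steel,Grocery,0.018,FALSE
Oak and Steel,Restaurant,0.411,FALSE
Oak and Steel,JuiceCoffee,0.075,FALSE
Oak and Steel,SpecialtyFoods,0.031,FALSE
Oak and Steel,SweetsDesserts,0.009,FALSE
La Vina Deli Grocery,AlcoholBar,0.006,FALSE
La Vina Deli Grocery,AlcoholStore,0.003,FALSE
La Vina Deli Grocery,Convenience,0.885,TRUE
La Vina Deli Grocery,Discount,0.003,FALSE
La Vina Deli Grocery,FastFood,0.942,TRUE
La Vina Deli Grocery,Grocery,0.069,FALSE
La Vina Deli Grocery,Restaurant,0.009,FALSE
La Vina Deli Grocery,JuiceCoffee,0.008,FALSE
La Vina Deli Grocery,SpecialtyFoods,0.038,FALSE
La Vina Deli Grocery,SweetsDesserts,0.008,FALSE
Butcher Bar,AlcoholBar,0.797,TRUE
Butcher Bar,AlcoholStore,0.010,FALSE
Butcher Bar,Convenience,0.007,FALSE
Butcher Bar,Discount,0.003,FALSE
Butcher Bar,FastFood,0.019,FALSE
Butcher Bar,Grocery,0.011,FALSE
Butcher Bar,Restaurant,0.597,TRUE
Butcher Bar,JuiceCoffee,0.018,FALSE
Butcher Bar,SpecialtyFoods,0.041,FALSE
Butcher Bar,SweetsDesserts,0.011,FALSE
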