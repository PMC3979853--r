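{"seed":42,"b":[0.68547922357333424,-0.28234908569804434,0.1815642056686696,0.3164313024805202,0.20213416157049952],"alpha_year":[0.223468870977129,0.62788049935973467],"lambda":[32.572853396551757,32.834481340151029,11.197056310122154,12.499028412682486,16.569509108265937,19.679238675123369,18.364717607402408,19.934089422833964,16.913872810758093,20.741450995625861],"N":[30,36,11,13,19,20,23,18,17,19],"p":[0.6786229822758838,0.68616383969652495,0.68321209900549718,0.76707398810470095,0.76707398810470095,0.76707398810470095,0.62254377285868123,0.62403898740025998,0.62385145283381926,0.68823108474487515,0.69069420163972972,0.68823108474487515,0.65417697769859917,0.65450630691730927,0.65417697769859917,0.74316534173082016,0.73727680222586689,0.74157905351123732,0.63640803908218946,0.63121920401799669,0.63121920401799669,0.69463153357768637,0.6961754448800942,0.69582809858959771,0.59325811402312567,0.59392322265552844,0.59325811402312567,0.76528250359581096,0.76528250359581096,0.76528250359581096],"params":{"beta0":2.4199999999999999,"trend":0.080000000000000002,"beta_water":{"water.wet":0.51000000000000001,"water.lt15":0.35999999999999999,"water.gt15":0.26000000000000001},"sigma_b":0.5,"alpha_year_mean":0.25,"alpha_year_sd":0.25,"alpha_rain":0.01,"alpha_veg":{"veg.41_80":0.65000000000000002,"veg.81_120":0.69999999999999996,"veg.gt120":0.14999999999999999}}}
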