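cohort,n,n_events,person_years,chd,mi,stroke,pad,revascularization,fatal_28d
hk_island_west,179953,16965,1288080,10877,1710,5384,715,2628,978
kowloon,522631,73551,4038513,40783,12921,31659,2004,3189,6576
new_territories,561293,67189,4303907,37562,10566,28450,1836,3814,4938
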