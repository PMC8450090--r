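{"bin_edges":[50,100,200,500,1000],"matrices":[[0.952410536779324,0.0475894632206759,0.0476116432392089,0.952388356760791],[0.907222357624502,0.0927776423754976,0.0945727669197222,0.905427233080278],[0.851194237330974,0.148805762669026,0.152873852345617,0.847126147654383],[0.749538782385498,0.250461217614502,0.253113349726343,0.746886650273658],[0.616719506090439,0.383280493909561,0.372559139784946,0.627440860215054],[0.54140127388535,0.45859872611465,0.440396179695791,0.559603820304209]],"counts":[[30659,1531,1530,30624],[11166,1141,1170,11210],[13470,2354,2430,13470],[18688,6244,6381,18831],[7391,4593,4330,7293],[1444,1223,1244,1581]]}
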