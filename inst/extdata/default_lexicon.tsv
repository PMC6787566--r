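food_name	taxid	excluded
broccoli	Brassica oleracea	FALSE
brussels sprouts	Brassica oleracea	FALSE
cabbage	Brassica oleracea	FALSE
cauliflower	Brassica oleracea	FALSE
kale	Brassica oleracea	FALSE
collard greens	Brassica oleracea	FALSE
kohlrabi	Brassica oleracea	FALSE
pumpkin	Cucurbita pepo	FALSE
zucchini	Cucurbita pepo	FALSE
hot pepper	Capsicum annuum	FALSE
bell pepper	Capsicum annuum	FALSE
orange	Citrus	FALSE
lemon	Citrus	FALSE
lime	Citrus	FALSE
grapefruit	Citrus	FALSE
tangerine	Citrus	FALSE
raspberry	Rubus	FALSE
blackberry	Rubus	FALSE
blueberry	Vaccinium	FALSE
strawberry	Fragaria	FALSE
beans	Phaseolus	FALSE
black beans	Phaseolus	FALSE
kidney beans	Phaseolus	FALSE
lima beans	Phaseolus	FALSE
apple	Malus/Pyrus	FALSE
pear	Malus/Pyrus	FALSE
rice	Poaceae	FALSE
rye	Poaceae	FALSE
wheat	Poaceae	FALSE
bread	Poaceae	FALSE
coffee	Coffea	FALSE
tea	Camellia sinensis	FALSE
cranberry	NA	TRUE
spices	NA	TRUE
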