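term	categories
bitter	bitter
bitterness	bitter
alkaloid	bitter
astringent	bitter
tart bitter	bitter
quinine	bitter
coffee	bitter,nutty
cocoa	bitter,nutty
cacao	bitter,nutty
dark chocolate	bitter
tea	bitter
hops	bitter
floral	floral
flower	floral
flowery	floral
rose	floral
violet	floral
jasmine	floral
lavender	floral
lilac	floral
geranium	floral
orange blossom	floral
honeysuckle	floral
hyacinth	floral
perfume	floral
perfumy	floral
muguet	floral
fruity	fruity
fruit	fruity
citrus	fruity
lemon	fruity
lime	fruity
orange	fruity
grapefruit	fruity
apple	fruity
green apple	fruity
pear	fruity
banana	fruity
grape	fruity
berry	fruity
strawberry	fruity
raspberry	fruity
blackberry	fruity
blueberry	fruity
cherry	fruity
peach	fruity
apricot	fruity
plum	fruity
pineapple	fruity
tropical	fruity
melon	fruity
mango	fruity
coconut	fruity,nutty
currant	fruity
off-flavor	off_flavor
off flavor	off_flavor
offflavor	off_flavor
rancid	off_flavor
musty	off_flavor
moldy	off_flavor
mouldy	off_flavor
putrid	off_flavor
rotten	off_flavor
sulfurous	off_flavor
sulfur	off_flavor
skunky	off_flavor
fishy	off_flavor
cardboard	off_flavor
stale	off_flavor
metallic	off_flavor
medicinal	off_flavor
phenolic	off_flavor
burnt	off_flavor
acrid	off_flavor
goaty	off_flavor
sweaty	off_flavor
cheesy	off_flavor
fatty	off_flavor
tallow	off_flavor
soapy	off_flavor
petroleum	off_flavor
solvent	off_flavor
earthy	off_flavor
smoky	off_flavor
onion	off_flavor
garlic	off_flavor
cabbage	off_flavor
nutty	nutty
nut	nutty
almond	nutty
hazelnut	nutty
peanut	nutty
walnut	nutty
roasted	nutty
toasted	nutty
popcorn	nutty
bready	nutty
malty	nutty
cereal	nutty
sour	sour
sourness	sour
acid	sour
acidic	sour
vinegar	sour
acetic	sour
tangy	sour
tart	sour
lactic	sour
yogurt	sour
sweet	sweet
sweetness	sweet
sugar	sweet
sugary	sweet
honey	sweet
caramel	sweet
caramellic	sweet
vanilla	sweet
syrup	sweet
molasses	sweet
candy	sweet
marshmallow	sweet
butterscotch	sweet
toffee	sweet
creamy	sweet
cream	sweet
buttery	sweet
milky	sweet
chocolate	sweet,bitter
jammy	sweet,fruity
winey	fruity,sour
balsamic	sweet
anise	sweet
licorice	sweet
mint	sweet
green	fruity
grassy	fruity
herbal	floral
woody	nutty
spicy	off_flavor
pungent	off_flavor
ammonia	off_flavor
amine	off_flavor
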