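aardvark
alligator
alpaca
ant
anteater
antelope
armadillo
baboon
badger
bat
bear
beaver
bee
beetle
bird
bison
boar
bobcat
buffalo
bull
butterfly
camel
canary
cardinal
caribou
cat
caterpillar
centipede
chameleon
cheetah
chicken
chimpanzee
chinchilla
chipmunk
clam
cobra
cockroach
cougar
cow
coyote
crab
crane
cricket
crocodile
crow
deer
dingo
dog
dolphin
donkey
dove
dragonfly
duck
eagle
eel
elephant
elk
emu
falcon
ferret
finch
fish
flamingo
fly
fox
frog
gazelle
gecko
gerbil
gibbon
giraffe
gnat
gnu
goat
goldfish
goose
gopher
gorilla
grasshopper
groundhog
guppy
hamster
hare
hawk
hedgehog
hen
heron
hippopotamus
hornet
horse
hummingbird
hyena
iguana
jackal
jaguar
jellyfish
kangaroo
koala
ladybug
lamb
lemur
leopard
lion
lizard
llama
lobster
lynx
macaw
meerkat
mole
mongoose
monkey
moose
mosquito
moth
mouse
mule
muskrat
newt
octopus
opossum
orangutan
ostrich
otter
owl
ox
panda
panther
parakeet
parrot
peacock
pelican
penguin
pig
pigeon
platypus
pony
porcupine
possum
puma
python
rabbit
raccoon
ram
rat
rattlesnake
raven
reindeer
rhinoceros
robin
rooster
salamander
salmon
seal
shark
sheep
shrimp
skunk
sloth
snail
snake
sparrow
spider
squid
squirrel
starfish
stork
swan
tiger
toad
tortoise
toucan
trout
tuna
turkey
turtle
viper
vulture
walrus
wasp
weasel
whale
wolf
wolverine
wombat
woodpecker
worm
yak
zebra
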