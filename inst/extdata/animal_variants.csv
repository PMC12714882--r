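variant,root
aardvarks,aardvark
alligators,alligator
alpacas,alpaca
anteaters,anteater
antelopes,antelope
ants,ant
armadillos,armadillo
baboons,baboon
badgers,badger
bats,bat
bears,bear
beavers,beaver
bees,bee
beetles,beetle
birdie,bird
birds,bird
boars,boar
bobcats,bobcat
buffalos,buffalo
bulls,bull
bunnies,rabbit
bunny,rabbit
butterflies,butterfly
camels,camel
canaries,canary
cardinals,cardinal
caribous,caribou
caterpillars,caterpillar
cats,cat
centipedes,centipede
chameleons,chameleon
cheetahs,cheetah
chickens,chicken
chimp,chimpanzee
chimpanzees,chimpanzee
chimps,chimpanzee
chinchillas,chinchilla
chipmunks,chipmunk
clams,clam
cobras,cobra
cockroaches,cockroach
cougars,cougar
cows,cow
coyotes,coyote
crabs,crab
cranes,crane
crickets,cricket
crocodiles,crocodile
crows,crow
dingos,dingo
doggy,dog
dogs,dog
dolphins,dolphin
donkeys,donkey
doves,dove
dragonflies,dragonfly
ducks,duck
eagles,eagle
eels,eel
elefant,elephant
elephants,elephant
emus,emu
falcons,falcon
ferrets,ferret
finches,finch
flamingos,flamingo
flies,fly
foxes,fox
frogs,frog
gator,alligator
gazelles,gazelle
geckos,gecko
geese,goose
gerbils,gerbil
gibbons,gibbon
girafe,giraffe
giraffes,giraffe
gnats,gnat
gnus,gnu
goats,goat
goldfishes,goldfish
gophers,gopher
gorillas,gorilla
grasshoppers,grasshopper
groundhogs,groundhog
guppies,guppy
hamsters,hamster
hares,hare
hawks,hawk
hedgehogs,hedgehog
hens,hen
herons,heron
hippo,hippopotamus
hippopotamuses,hippopotamus
hippos,hippopotamus
hornets,hornet
horses,horse
hummingbirds,hummingbird
hyenas,hyena
iguanas,iguana
jackals,jackal
jaguars,jaguar
jellyfishes,jellyfish
kangaroos,kangaroo
kitten,cat
kittens,cat
kitty,cat
koalas,koala
ladybugs,ladybug
lambs,lamb
lemurs,lemur
leopards,leopard
lions,lion
lizards,lizard
llamas,llama
lobsters,lobster
lynxes,lynx
macaws,macaw
meerkats,meerkat
mice,mouse
moles,mole
mongooses,mongoose
monkeys,monkey
monkies,monkey
mosquitos,mosquito
moths,moth
mules,mule
muskrats,muskrat
newts,newt
octopi,octopus
octopuses,octopus
opossums,opossum
orangutans,orangutan
ostriches,ostrich
otters,otter
owls,owl
oxen,ox
pandas,panda
panthers,panther
parakeets,parakeet
parrots,parrot
peacocks,peacock
pelicans,pelican
penguins,penguin
pigeons,pigeon
pigs,pig
platypuses,platypus
ponies,pony
porcupines,porcupine
possums,possum
pumas,puma
puppies,dog
puppy,dog
pythons,python
rabbits,rabbit
raccoons,raccoon
rams,ram
rats,rat
rattlesnakes,rattlesnake
ravens,raven
reindeers,reindeer
rhino,rhinoceros
rhinoceroses,rhinoceros
rhinos,rhinoceros
roach,cockroach
robins,robin
roosters,rooster
salamanders,salamander
salmons,salmon
seals,seal
sharks,shark
shrimps,shrimp
skunks,skunk
sloths,sloth
snails,snail
snakes,snake
sparrows,sparrow
spiders,spider
squids,squid
squirrels,squirrel
starfishes,starfish
storks,stork
swans,swan
tigers,tiger
toads,toad
tortoises,tortoise
toucans,toucan
trouts,trout
tunas,tuna
turkeys,turkey
turtles,turtle
vipers,viper
vultures,vulture
walruses,walrus
wasps,wasp
weasels,weasel
whales,whale
wolverines,wolverine
wolves,wolf
wombats,wombat
woodpeckers,woodpecker
worms,worm
yaks,yak
zebras,zebra
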