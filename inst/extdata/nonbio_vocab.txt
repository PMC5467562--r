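the
of
and
to
in
that
was
his
her
with
for
had
not
but
at
by
which
have
from
this
him
they
were
she
are
been
their
one
all
we
when
there
would
who
what
so
out
if
will
can
more
about
into
them
then
some
could
time
these
two
may
first
now
people
my
made
over
did
new
also
after
our
other
many
most
through
before
where
much
your
way
well
should
because
each
just
those
house
world
still
own
see
men
work
long
here
between
life
being
under
never
day
same
another
know
while
last
might
great
old
year
off
come
since
against
little
three
place
right
without
look
city
think
say
went
back
home
school
every
found
thought
part
once
water
even
again
took
left
always
away
something
fact
though
less
got
far
took
hand
school
until
better
nothing
night
end
why
called
eyes
find
going
look
asked
later
knew
point
next
room
got
book
among
along
shall
told
felt
says
table
door
open
walked
morning
evening
early
light
money
public
become
across
however
town
road
garden
window
music
paper
letter
winter
summer
spring
autumn
river
bridge
forest
mountain
weather
coffee
dinner
breakfast
kitchen
family
friend
father
mother
brother
sister
children
teacher
student
doctor
lawyer
driver
baker
market
street
corner
church
castle
village
country
island
harbor
ship
train
station
ticket
journey
holiday
picture
painting
colour
green
blue
yellow
black
white
brown
silver
golden
heavy
quiet
noisy
gentle
sudden
slowly
quickly
carefully
happily
sadly
bright
dark
clean
dirty
empty
whole
broken
wooden
stone
glass
plastic
cotton
woolen
jacket
pocket
button
ribbon
basket
bottle
kettle
saucer
spoon
knife
plate
candle
carpet
curtain
pillow
blanket
ladder
hammer
needle
thread
string
button
garden
flower
grass
leaves
branch
apple
orange
banana
cherry
potato
carrot
onion
butter
cheese
honey
sugar
bread
dinner
supper
barking
singing
dancing
reading
writing
playing
walking
running
jumping
swimming
laughing
crying
sleeping
dreaming
talking
listening
watching
waiting
driving
riding
flying
sailing
cooking
cleaning
washing
painting
drawing
building
digging
planting
watering
weather
cloudy
sunny
rainy
windy
stormy
foggy
frosty
chilly
pleasant
curious
serious
famous
careful
helpful
cheerful
thankful
peaceful
powerful
beautiful
wonderful
terrible
horrible
possible
probable
suitable
valuable
ordinary
necessary
library
history
century
moment
minute
second
hour
week
month
season
evening
afternoon
midnight
tomorrow
yesterday
today
already
perhaps
almost
enough
rather
quite
indeed
instead
besides
therefore
meanwhile
anyway
somewhere
anywhere
everywhere
nowhere
somebody
anybody
everybody
nobody
anything
everything
neither
either
whose
theirs
ours
mine
yours
itself
himself
herself
themselves
ourselves
yourself
myself
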