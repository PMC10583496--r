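the	60000
and	28000
a	22000
to	26000
of	30000
in	18000
is	10000
it	9000
you	14000
that	11000
he	9000
was	9500
for	8800
on	7000
are	4600
with	7000
as	5500
i	25000
his	5500
they	4300
be	6500
at	5300
one	3400
have	4500
this	5000
from	4300
or	3800
had	2600
by	5000
not	4500
word	120
but	4400
what	2400
some	1600
we	5200
can	2100
out	1800
other	1300
were	1700
all	2700
there	2200
when	2300
up	2000
use	500
your	2900
how	1500
said	900
an	2400
each	450
she	3300
which	1600
do	3000
their	1900
time	1600
if	2300
will	2700
way	900
about	2400
many	700
then	1100
them	1400
would	1800
like	2400
so	3700
these	800
her	3000
long	500
make	1000
thing	500
see	1400
him	1500
two	900
has	2200
look	800
more	2000
day	600
could	1300
go	1900
come	1100
did	1200
my	3900
no	2900
most	900
who	1700
over	1100
know	2100
water	250
than	1300
call	300
first	800
people	1200
may	900
down	900
side	250
been	1300
now	1800
find	600
any	900
new	1000
work	800
part	400
take	900
get	2300
place	400
made	600
live	300
where	1100
after	800
back	1100
little	600
only	1200
round	120
man	700
year	700
came	400
show	500
every	500
good	1400
me	4100
give	700
our	1400
under	400
um	350
uh	300
hmm	40
er	25
eh	20
mm	30
stuff	150
things	600
something	800
someone	250
anything	350
cat	80
dog	110
tree	90
house	300
mother	300
boy	200
girl	250
cookie	25
jar	15
kitchen	120
window	130
chair	70
table	150
fall	200
falling	60
wash	40
washing	30
dishes	25
reach	90
reaching	20
ladder	12
lightbulb	3
kitten	8
branch	40
climb	30
climbing	25
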