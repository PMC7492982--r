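%
1	funct
2	pronoun
3	ppron
4	i
5	we
6	you
7	shehe
8	they
9	ipron
10	article
11	verb
12	auxverb
13	past
14	present
15	future
16	adverb
17	preps
18	conj
19	negate
20	quant
21	number
22	swear
23	social
24	family
25	friend
26	humans
27	affect
28	posemo
29	negemo
30	anx
31	anger
32	sad
33	cogmech
34	insight
35	cause
36	discrep
37	tentat
38	certain
39	inhib
40	incl
41	excl
42	percept
43	see
44	hear
45	feel
46	bio
47	body
48	health
49	sexual
50	ingest
51	relativ
%
the	1 10
a	1 10
an	1 10
to	1 17
of	1 17
i	1 2 3 4
we	1 2 3 5
you	1 2 3 6
she	1 2 3 7
he	1 2 3 7
they	1 2 3 8
it	1 2 9
that	1 2 9
anyone	1 2 9
something	1 2 9
anything	1 2 9
someone	1 2 9
nothing	1 2 9
whatever	1 2 9
everyone	1 2 9
somebody	1 2 9
nobody	1 2 9
itself	1 2 9
go	11 14 51
went	11 13
going	11 14
will	11 12 15
was	11 12 13
is	11 12 14
are	11 12 14
can	11 12
could	11 12
do	11 12 14
really	16
very	16
quickly	16
always	16 38
no	19
not	19
never	16 19
cannot	19
dont	19
wont	19
in	17
on	17
at	17
from	17
about	17
over	17
under	17
between	17
through	17
during	17
above	17 51
with	17 40
and	18 40
but	18 41
or	18 41
because	18 33 35
so	18
if	18
few	20
many	20
much	20
more	20
most	20
less	20
lots	20
several	20
plenty	20
every	20
some	20
all	20
bunch	20
one	21
two	21
three	21
first	21
second	21
damn	22
hell	22
talk	23
friend	23 25
family	23 24
mother	23 24
father	23 24
sister	23 24
brother	23 24
buddy	23 25
neighbor	23 26
people	23 26
person	23 26
happy	27 28
good	27 28
great	27 28
love	27 28
nice	27 28
sweet	27 28
fun	27 28
hope	27 28
glad	27 28
joy	27 28
awesome	27 28
excited	27 28
beautiful	27 28
laugh	27 28
happi*	27 28
bad	27 29
awful	27 29
terrible	27 29
horrible	27 29
nasty	27 29
ugly	27 29
nervous	27 29 30
anxious	27 29 30
worried	27 29 30
worry	27 29 30
tense	27 29 30
afraid	27 29 30
scared	27 29 30
fear	27 29 30
panic	27 29 30
stress	27 29 30
stressed	27 29 30
uneasy	27 29 30
dread	27 29 30
angry	27 29 31
anger	27 29 31
mad	27 29 31
hate	27 29 31
rage	27 29 31
furious	27 29 31
annoyed	27 29 31
irritated	27 29 31
pissed	27 29 31
hostile	27 29 31
outraged	27 29 31
resent	27 29 31
sad	27 29 32
sadness	27 29 32
cry	27 29 32
crying	27 29 32
tears	27 29 32
grief	27 29 32
lonely	27 29 32
miserable	27 29 32
hopeless	27 29 32
gloomy	27 29 32
sorrow	27 29 32
depress*	27 29 32
think	33 34
know	33 34
understand	33 34
realize	33 34
believe	33 34
consider	33 34
wonder	33 34
aware	33 34
meaning	33 34
learn	33 34
figure	33 34
insight	33 34
cause	33 35
effect	33 35
why	33 35
since	33 35
hence	33 35
should	33 36
would	33 36
wish	33 36
want	33 36
need	33 36
maybe	33 37
perhaps	33 37
guess	33 37
seem	33 37
unsure	33 37
sure	33 38
certain	33 38
definitely	33 38
totally	33 38
block	33 39
stop	33 39
constrain	33 39
restrain	33 39
avoid	33 39
forbid	33 39
prevent	33 39
control	33 39
limit	33 39
ban	33 39
refuse	33 39
restrict	33 39
quit	33 39
includ*	33 40
add	33 40
along	33 40
both	33 40
plus	33 40
together	33 40
inclusive	33 40
combine	33 40
join	33 40
without	33 41
except	33 41
exclude	33 41
observe	42
notice	42
perceive	42
see	42 43
saw	42 43
look	42 43
looking	42 43
watch	42 43
view	42 43
sight	42 43
stare	42 43
glance	42 43
bright	42 43
hear	42 44
heard	42 44
hearing	42 44
listen	42 44
listened	42 44
listening	42 44
sound	42 44
sounds	42 44
noise	42 44
loud	42 44
voice	42 44
voices	42 44
whisper	42 44
music	42 44
feel	42 45
felt	42 45
touch	42 45
touched	42 45
soft	42 45
rough	42 45
life	46
alive	46
sleep*	46 48
head	46 47
arm	46 47
leg	46 47
hand	46 47
skin	46 47
heart	46 47
blood	46 47
brain	46 47
stomach	46 47
eyes	46 47
face	46 47
body	46 47
health	46 48
healthy	46 48
sick	46 48
ill	46 48
illness	46 48
doctor	46 48
hospital	46 48
medicine	46 48
medication	46 48
clinic	46 48
pill	46 48
symptom	46 48
symptoms	46 48
flu	46 48
pain	46 48
therapy	46 48
nurse	46 48
sex	46 49
sexual	46 49
sexy	46 49
naked	46 49
porn	46 49
kiss	46 49
horny	46 49
lust	46 49
dating	46 49
hookup	46 49
condom	46 49
fuck	22 46 49
eat	46 50
food	46 50
drink	46 50
hungry	46 50
meal	46 50
dinner	46 50
lunch	46 50
breakfast	46 50
pizza	46 50
coffee	46 50
time	51
now	51
today	51
tomorrow	51
yesterday	51
soon	51
early	51
late	51
before	51
here	51
there	51
far	51
up	51
down	51
move	51
moving	51
come	51
arrive	51
week	51
month	51
year	51
morning	51
night	51
hour	51
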