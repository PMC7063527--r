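; Opinion-lexicon negative word list -- SUBSET shipped with stimtweet.
; A curated subset of a standard English opinion lexicon (negative polarity),
; one word per line, ';' lines are comments. Supply full lists via
; load_sentiment_lexicon() for production use.
abuse
addict
addicted
afraid
angry
annoyed
annoying
anxious
ashamed
awful
bad
badly
bitter
broke
broken
crap
crash
crazy
cried
cry
crying
damn
dangerous
dead
depressed
desperate
dizzy
dread
dying
exhausted
fail
failed
fear
freaking
fried
frustrated
gross
hard
hate
hated
hell
horrible
hurt
hurts
ill
insane
irritable
jittery
kill
lost
mad
mess
miserable
moody
nasty
nauseous
nervous
nightmare
numb
pain
painful
panic
paranoid
pathetic
problem
problems
psycho
regret
restless
rough
ruin
ruined
sad
scared
scary
shaky
sick
sore
stress
stressed
struggle
struggling
stupid
suck
sucks
suffer
terrible
tired
toxic
ugly
unbearable
upset
weird
worse
worst
worthless
wrong
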