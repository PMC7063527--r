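; Opinion-lexicon positive word list -- SUBSET shipped with stimtweet.
; A curated subset of a standard English opinion lexicon (positive polarity),
; one word per line, ';' lines are comments. Supply full lists via
; load_sentiment_lexicon() for production use.
amazing
awesome
beautiful
benefit
best
better
bliss
brilliant
calm
celebrate
cheerful
clarity
clear
comfortable
confident
delight
delighted
easy
effective
efficient
encouraging
energetic
enjoy
enjoyed
excellent
excited
fabulous
fantastic
fine
focused
fortunate
free
fresh
fun
glad
good
grateful
great
happier
happiness
happy
heal
healthy
helpful
helps
hope
hopeful
impressed
improve
improved
incredible
joy
kind
like
liked
love
loved
lovely
lucky
motivated
nice
optimistic
peaceful
perfect
pleasant
pleased
positive
productive
proud
recommend
refreshed
relaxed
relief
relieved
rescue
safe
satisfied
smart
smile
smooth
steady
strong
succeed
success
super
thankful
thrilled
top
useful
win
wonderful
works
worthy
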