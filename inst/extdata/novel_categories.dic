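%
1	simple_affective_states
2	complex_affective_states
3	affective_behaviors
4	cognitive_states
5	cognitive_behaviors
6	causal
7	story_elements
8	characters
%
happy	1
happi*	1
sad	1
angry	1
angri*	1
afraid	1
disgust*	1
surprise*	1
joy*	1
mad	1
shame	2
asham*	2
pride	2
proud	2
guilt*	2
hug*	3
smil*	3
cry	3
cries	3
crying	3
shudder*	3
cower*	3
know	4
knows	4
knew	4
hope*	4
think*	4
thought	4
believe*	4
escape*	5
follow*	5
hide	5
hides	5
hiding	5
hid	5
attack*	5
because	6
since	6
therefore	6
as a result	6
in order to	6
branch*	7
family	7
antler*	7
deer	8
dog	8
boy	8
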