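word	cluster
myself	self
person	self
name	self
years	self
singapore	self
live	self
family	self
friends	self
people	self
interesting	self
really	self
think	self
enjoy	hobby
music	hobby
playing	hobby
guitar	hobby
sports	hobby
running	hobby
reading	hobby
books	hobby
movies	hobby
games	hobby
drawing	hobby
cooking	hobby
school	work
study	work
class	work
teacher	work
project	work
working	work
job	work
learn	work
exam	work
course	work
computer	work
science	work
feel	feeling
happy	feeling
nervous	feeling
excited	feeling
hope	feeling
want	feeling
like	feeling
love	feeling
good	feeling
great	feeling
better	feeling
sometimes	feeling
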