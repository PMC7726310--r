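breed,risk_group
Australian terrier,high
Samoyed,high
Swedish lapphund,high
Swedish elkhound,high
Border collie,high
Finnish hound,high
Drever,high
West Highland white terrier,high
Hamilton hound,high
Miniature poodle,high
Toy poodle,high
Jack Russell terrier,low
Miniature dachshund,low
German shepherd,low
Rough haired collie,low
Standard poodle,low
Soft coated wheaten terrier,low
Bearded collie,low
Golden retriever,low
Boxer,low
Papillon,low
Labrador retriever,moderate
Mixed breed,moderate
Cocker spaniel,moderate
Rottweiler,moderate
Shetland sheepdog,moderate
Dachshund,moderate
Flat coated retriever,moderate
Beagle,moderate
Whippet,moderate
Staffordshire bull terrier,moderate
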