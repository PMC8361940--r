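>CHI_era synthetic stand-in reference sequence; annotated pocket positions follow the bacterial chalcone isomerase literature
PYKYNMYQPIAIKVCYHHGERCEEATNAIYMEHRTPSGEQFVHYMNDYPFLKTYCYNPYQ
TFSTQLMDEHTNHNWFGWDHANYYIPKFLAEHPMVGYIDLQKKSETIQSARAKPTCDQNQ
QNKNRHDYNKLMKGFVNVTKGYFFFSTSIDRECHPHRLWWFEPKEDAEGDLESQHGQVPA
PYDNCMGPLHVHMRWGMIWGIEMEYTQQHI
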