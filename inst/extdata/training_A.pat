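>Z*A|variant=A|style=Z
.....
#####
...#.
..#..
.#...
#####
.....
>H*A|variant=A|style=H
.....
..#..
#.#.#
#####
#.#.#
..#..
.....
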