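# Built-in particle library in .cells-style blocks: '! name' headers,
# 'O' = alive, '.' = dead.  Same set as gol_library()'s default.
! glider
.O.
..O
OOO
! lwss
.O..O
O....
O...O
OOOO.
! blinker
OOO
! block
OO
OO
! beehive
.OO.
O..O
.OO.
! loaf
.OO.
O..O
.O.O
..O.
! boat
OO.
O.O
.O.
! tub
.O.
O.O
.O.
! ship
OO.
O.O
.OO
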