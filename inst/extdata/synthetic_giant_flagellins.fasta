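>giant_syn1 synthetic giant flagellin (generator preset, not a database record)
ICLEKKDAYINARQHNVLVQMSVKYWSGGYMLQAWKPRICVLQSYIVQPPHWQRFTKRSR
DDTMQWVRKQIEQMINCMPCMRSTYSKQVVTGVPRKINTHEPATHFCEMPTMMSNEYKLD
EESVVAYDGWLFHEQHTFQYGHMAICHMTMWGQVMITYIQSELHEVHFSAKIFNEGNHNS
RENHAAPVQESKCIDWNAQFGTYRGNLTDQPRQKPRRYCATYDVMYMGCKCGVGGIYNPV
FFIGLRKLLDYPQMNESQFHKGYHARKWQEIGHQLWTQFSVPLVHARQSYREIVSTQHKC
CHADDENHQCVSSMVWAWYGAMVPVIQDFLWWEYRRWPMMSADQFDASLARPVYFKMLSE
VLWYDKSYCAYFDNTMIGTHIPINNATQGLEGCSDKHGSRYFRCQMVMNWIPHFHCCATG
PHYPSRQYNMSPAIQLLQQYMGGILFDMEGIVRLIPEMFCRPRELQKHFYCDHDNHSEER
AYEFQFCKHGQVVGGIGGGPGGGGGGEGYGGGGGGSIGGGIQAGPGGGVGTTLCLWWIFA
WECWPQMMANIPELFAGPKQHQFDCHGGWHWINYMRWAYYRENHAAPVQESKCIDWNAQF
GTYRGHLTDQPRQKPRRYCADYDVMYMGCKCAVGGIYNPVFFIGLRKLLDYPQMNESQFL
KGYHARKWQEIGHQLWTQFSVPLVHARQSYREIVSTQHKVCHADDENHQTVSHMVWAQYG
AMVHVIQIFLWWEFRRSKMMNADQFDASLARPHYFKMLIEVLWYDKSYCTKFDNTMIGTH
IPIKNAHQGLEGCSDKHGYRYVRCPMVMNWIPHFHCCATGPTYPSRQYNMSPAIQLNQQY
APDMVFKTPATWHPFRELYKAGNPVKEPVFGTAVKRWYMFLIDIAAGDTLNCWNQYLNKG
LNRARTSIHWNIYGIKCGTEQWGAICNLSCPETAKAQQIVYHHWDMRTGDPMTSDGCVED
YLMRRLPCSSKYFMETDFSRKGHIHPPKFNWITLRDNMCWCGKEMVSMVYRTNDVFLAF
>giant_syn2 synthetic giant flagellin (generator preset, not a database record)
ICEEKKDAYINAVQRNVLVQMSVKYWSGGYMLQAWKPRICVLQSYIVQPGMWQRFTKLST
DDTMQWKRKQIEQMINCMPCMRSTYSKQVWTGVVRKINTHEPATDFCEMPTMMSNDYKLD
KESVVARDGYLFHEQHTFQYGHLAICHMTMEGQVMITYIQSELHEVHFSAKIFNEGNHNS
RENHAAPVQESKCIDWNGQFGTSRGHLTDQPRQKPRRYCADYDVWYMGTKCGVFGIYNPV
FFIGLRKLLDYPQMNESQFHKGYHARKWQEIGHQLWTQFSVPLVHARQSYAEHVSTQMKV
QHADDENHQTVSSMVWAWYGAMVPVIQIFLWWEFRRSKIMDADQFDASLARPIYFKMLSE
VLWYDKSYCAKFDNTMISTHIPIKNATQGLEGCSDKHGSRYFRCQMVMNWIPHFHCCATG
PHRPSRQYNYSPAIQLLQQYMGGILTDMEGIVRLIPEMFCRPRELRKHFYCDHDNHSEER
KYEFQFCKMGQVVGGGGGGPGGGGGGQGYGGMGGGSGGGGKQAGPGGGVGTELCLWWIFA
WECWTQMMANDPELFAGKKQHQFDCSGGWHWINYMAWAYYRENHAAPVQESKCIDWNAQF
GTRRGHLTDQPRQKPRRYCADYDVMYMGCKCGVGGIYNKVFFIGLRKSLDMPQMNESQFQ
KPYHARKWQEKGHQLWTQFSVPLVHARQSYREIVSTQHKVCHADDELHQTVSSMVQAWYG
AMVPVIQIFLWWEFRRSKMMNADQFDASLARPVYFKMLIEVLWYDKSYWAKFDNTMIGTH
IPIKNATQGLEGCSDKHGSRYFRCNMVMNWIPHEHCCATGPHYLSRQYNMSPAIQLLQQY
APDMVFKTPATWHIFRELYKAGNPVKEPVCGTAVKRWYMFLIDEIAAGDTLNCWNQYLNK
GLNRARTSIHWNIYGIKCPTEQWGAICNLDKPETFKTQQIVYHHWDMRTGDPMWSDGYVE
DYLMWRLGCSSKQFMETDFSRKGHYGSPKFNWINQRDNMCWCGKEMVSFVYRTNDVFLAF
>giant_syn3 synthetic giant flagellin (generator preset, not a database record)
ICLEKKDAYINARQHNVLVQMSVKYWSGGYMLQAWKPRICVLQSYIVQPPHWQRFTKRST
DDTMQWVRKQIEQMINCMPCMRSTYSKQVVTGVPRKINTHEPATHFCEMMTMMSNEYKLD
EESVVAYDGWLFHEQHTFQYGHLAICHMTMWGQVMITYIQSELHEVHFSAKIFNEGNHNS
RENHAAPVQESKCIDWNAQFGTYRGNLTDQPRQKWRRYCADYDVMYMGCKCGVGGIYNPV
FFIGLRKLLDYPQMNESQFHKGYHARKWQEIGHQLWTQFSVPLVHARQSYREIVSTQHKC
CHADDENHQCVSSMVWAWYGAMVPVIQLFLWWEYRRSKMMSADQFDASLARPVYFKMLSE
VLWYDKSICAYFDNTMIGTHIPIKNATQGLEGCSDKHGSRYFRCQMVMNWIPHFHCCATG
PHYPSRQYNMSPAIQMLQQYMGGILFDMEGIVRLIPEMFCRPRELQKHFYCDHCNHSEER
AYEFQFCKHGQVVGGGGGGPGGGGGGEGYGGGGGGSGGGGIQAGPGGGVGTTLCLWWIFA
WECWHQMMANIPELFAGPKQHQFDCHGGWHWINYMRWAYYRENHAAPVQESKCIDWNAQF
GTYRGHLTDQPRQKPRRYCADYDVMYMGCKCGVGGIYNPVFFIGLRKLLDYPQMNESQFL
KGYHARKWQEIGHQLWTQFSVPLVHARQSYREIVSTQHKVCHAFDENHQTVIHMVWAQYG
AMVHVIQIFLWWEFRRSKMMNADQFDASLARPHYFKMLIEVLWYDKSYCTKFDNTMIGTH
IVIKNAHQGLEGCSDKHGYRYVRCPMVMNWIPHFKCCATGPTYPSRQYNMSPAIQLNQQY
APDMVFKTPATWHPFRELYKQGNPVKEPVFGTAVKRWYMFLIDIAAGDTLNCWNQYLNKG
LNRARTSIHWNIYGIKCGTEQWGAICNLSCPETAKTQQIVYHHWDMRTGDPMTSDGCVED
YLMRRLGCSSKYFMETDFSRKGHYHPPKFNWITLRDNMCWCGKEMVSMVYRTNDVFLAF
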