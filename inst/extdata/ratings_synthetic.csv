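"item","rater_a","rater_b"
"img01",6,6
"img02",2,2
"img03",7,7
"img04",5,5
"img05",5,5
"img06",5,5
"img07",5,5
"img08",8,8
"img09",4,4
"img10",3,3
"img11",8,8
"img12",4,3
"img13",8,8
"img14",9,9
"img15",7,6
"img16",6,6
"img17",5,5
"img18",15,15
"img19",8,7
"img20",4,4
"img21",15,15
"img22",7,6
"img23",4,3
"img24",7,6
"img25",4,3
"img26",6,6
"img27",8,8
"img28",9,9
"img29",7,7
"img30",5,5
"img31",6,6
"img32",9,9
"img33",6,6
"img34",7,6
"img35",6,6
"img36",5,5
"img37",5,4
"img38",3,3
"img39",2,2
"img40",6,6
"img41",7,7
"img42",5,4
"img43",7,7
"img44",7,7
"img45",3,3
"img46",8,8
"img47",7,7
"img48",5,5
"img49",4,4
"img50",5,5
"img51",6,6
"img52",6,6
"img53",4,4
"img54",7,6
"img55",6,6
"img56",9,9
"img57",6,6
"img58",15,15
"img59",7,7
"img60",5,5
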