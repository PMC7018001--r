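graph [
  node [
    id 0
    label "0"
  ]
  node [
    id 1
    label "1"
  ]
  node [
    id 2
    label "2"
  ]
  node [
    id 3
    label "3"
  ]
  node [
    id 4
    label "4"
  ]
  node [
    id 5
    label "5"
  ]
  node [
    id 6
    label "6"
  ]
  node [
    id 7
    label "7"
  ]
  node [
    id 8
    label "8"
  ]
  node [
    id 9
    label "10"
  ]
  node [
    id 10
    label "11"
  ]
  node [
    id 11
    label "12"
  ]
  node [
    id 12
    label "13"
  ]
  node [
    id 13
    label "17"
  ]
  node [
    id 14
    label "19"
  ]
  node [
    id 15
    label "21"
  ]
  node [
    id 16
    label "31"
  ]
  node [
    id 17
    label "30"
  ]
  node [
    id 18
    label "9"
  ]
  node [
    id 19
    label "27"
  ]
  node [
    id 20
    label "28"
  ]
  node [
    id 21
    label "32"
  ]
  node [
    id 22
    label "16"
  ]
  node [
    id 23
    label "33"
  ]
  node [
    id 24
    label "14"
  ]
  node [
    id 25
    label "15"
  ]
  node [
    id 26
    label "18"
  ]
  node [
    id 27
    label "20"
  ]
  node [
    id 28
    label "22"
  ]
  node [
    id 29
    label "23"
  ]
  node [
    id 30
    label "25"
  ]
  node [
    id 31
    label "29"
  ]
  node [
    id 32
    label "24"
  ]
  node [
    id 33
    label "26"
  ]
  edge [
    source 0
    target 1
  ]
  edge [
    source 0
    target 2
  ]
  edge [
    source 0
    target 3
  ]
  edge [
    source 0
    target 4
  ]
  edge [
    source 0
    target 5
  ]
  edge [
    source 0
    target 6
  ]
  edge [
    source 0
    target 7
  ]
  edge [
    source 0
    target 8
  ]
  edge [
    source 0
    target 9
  ]
  edge [
    source 0
    target 10
  ]
  edge [
    source 0
    target 11
  ]
  edge [
    source 0
    target 12
  ]
  edge [
    source 0
    target 13
  ]
  edge [
    source 0
    target 14
  ]
  edge [
    source 0
    target 15
  ]
  edge [
    source 0
    target 16
  ]
  edge [
    source 1
    target 2
  ]
  edge [
    source 1
    target 3
  ]
  edge [
    source 1
    target 7
  ]
  edge [
    source 1
    target 12
  ]
  edge [
    source 1
    target 13
  ]
  edge [
    source 1
    target 14
  ]
  edge [
    source 1
    target 15
  ]
  edge [
    source 1
    target 17
  ]
  edge [
    source 2
    target 3
  ]
  edge [
    source 2
    target 7
  ]
  edge [
    source 2
    target 8
  ]
  edge [
    source 2
    target 18
  ]
  edge [
    source 2
    target 12
  ]
  edge [
    source 2
    target 19
  ]
  edge [
    source 2
    target 20
  ]
  edge [
    source 2
    target 21
  ]
  edge [
    source 3
    target 7
  ]
  edge [
    source 3
    target 11
  ]
  edge [
    source 3
    target 12
  ]
  edge [
    source 4
    target 6
  ]
  edge [
    source 4
    target 9
  ]
  edge [
    source 5
    target 6
  ]
  edge [
    source 5
    target 9
  ]
  edge [
    source 5
    target 22
  ]
  edge [
    source 6
    target 22
  ]
  edge [
    source 8
    target 17
  ]
  edge [
    source 8
    target 21
  ]
  edge [
    source 8
    target 23
  ]
  edge [
    source 12
    target 23
  ]
  edge [
    source 14
    target 23
  ]
  edge [
    source 16
    target 32
  ]
  edge [
    source 16
    target 30
  ]
  edge [
    source 16
    target 20
  ]
  edge [
    source 16
    target 21
  ]
  edge [
    source 16
    target 23
  ]
  edge [
    source 17
    target 21
  ]
  edge [
    source 17
    target 23
  ]
  edge [
    source 18
    target 23
  ]
  edge [
    source 19
    target 29
  ]
  edge [
    source 19
    target 32
  ]
  edge [
    source 19
    target 23
  ]
  edge [
    source 20
    target 23
  ]
  edge [
    source 21
    target 24
  ]
  edge [
    source 21
    target 25
  ]
  edge [
    source 21
    target 26
  ]
  edge [
    source 21
    target 27
  ]
  edge [
    source 21
    target 28
  ]
  edge [
    source 21
    target 29
  ]
  edge [
    source 21
    target 31
  ]
  edge [
    source 21
    target 23
  ]
  edge [
    source 23
    target 24
  ]
  edge [
    source 23
    target 25
  ]
  edge [
    source 23
    target 26
  ]
  edge [
    source 23
    target 27
  ]
  edge [
    source 23
    target 28
  ]
  edge [
    source 23
    target 29
  ]
  edge [
    source 23
    target 33
  ]
  edge [
    source 23
    target 31
  ]
  edge [
    source 29
    target 30
  ]
  edge [
    source 29
    target 31
  ]
  edge [
    source 30
    target 32
  ]
  edge [
    source 31
    target 33
  ]
]
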