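attributes: [ID, FirstName, LastName, SSN, DateOfBirth, Gender, SchoolID, MiddleName, SSID]
inputs:
  - path: Input01.csv
    map: [0, 1, 2, 3, 4, 5, 6, 7, 8]
  - path: Input02.csv
    map: [0, 1, 2, 3, -1, -1, -1, -1, -1]
  - path: Input03.csv
    map: [0, 1, 2, -1, 3, 4, 5, 6, 7]
comparisons:
  - edit:LastName
  - truncation:FirstName:1
block_attr: LastName
threshold: 1
avg_block_len: 7
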