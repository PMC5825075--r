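"person_id","episode_id","age","sex","los_days","drg","principal_dx","additional_dx","surgical","admission_date"
"p000001","e0000001",71,"male",6,"D004","K59","K25;K704;I50",FALSE,2007-02-20
"p000002","e0000002",78,"female",2,"D001","S72","",FALSE,2006-02-25
"p000003","e0000003",103,"male",5,"D003","M17","",FALSE,2006-05-31
"p000004","e0000004",94,"male",4,"D002","M17","",FALSE,2006-03-10
"p000005","e0000005",91,"male",1,"D004","M54","N390",FALSE,2006-06-18
"p000006","e0000006",67,"male",2,"D004","K59","L89",TRUE,2006-10-03
"p000007","e0000007",56,"male",1,"D002","H25","G30",FALSE,2005-07-12
"p000008","e0000008",72,"male",2,"D002","I10","",TRUE,2005-08-17
"p000009","e0000009",70,"female",17,"D004","J44","G31",TRUE,2006-06-08
"p000010","e0000010",56,"male",8,"D003","I10","",TRUE,2006-03-17
"p000011","e0000011",104,"male",1,"D005","K59","",TRUE,2007-02-24
"p000012","e0000012",54,"male",30,"D005","A09","F02",TRUE,2007-03-09
"p000013","e0000013",55,"female",29,"D005","J44","",TRUE,2006-01-31
"p000014","e0000014",67,"male",1,"D003","A09","M05",FALSE,2006-11-02
"p000015","e0000015",104,"female",1,"D005","M17","N390",FALSE,2007-03-01
"p000016","e0000016",81,"male",15,"D001","J44","F05",TRUE,2006-09-07
"p000017","e0000017",51,"male",2,"D003","J44","B20;N18;C18",FALSE,2006-11-10
"p000018","e0000018",84,"male",20,"D004","H25","I60;K25",FALSE,2007-03-14
"p000019","e0000019",82,"female",2,"D004","I10","",FALSE,2006-10-19
"p000020","e0000020",87,"male",2,"D001","H25","I50",TRUE,2005-09-29
"p000021","e0000021",77,"female",7,"D005","S72","",FALSE,2007-05-19
"p000022","e0000022",57,"male",26,"D001","E66","",FALSE,2006-03-19
"p000023","e0000023",68,"male",13,"D003","H25","",FALSE,2005-10-15
"p000024","e0000024",82,"male",1,"D001","I10","J16",FALSE,2005-08-15
"p000025","e0000025",58,"female",3,"D004","H25","",FALSE,2005-11-22
"p000026","e0000026",50,"male",1,"D002","J44","",TRUE,2006-12-07
"p000027","e0000027",98,"male",11,"D005","S72","M05",FALSE,2006-10-31
"p000028","e0000028",66,"male",2,"D002","R07","I50;L89",FALSE,2006-05-14
"p000029","e0000029",82,"female",11,"D005","M17","M05;E10",FALSE,2007-03-01
"p000030","e0000030",106,"female",10,"D001","K59","",TRUE,2006-10-29
"p000031","e0000031",99,"female",1,"D002","I10","M05",FALSE,2005-11-30
"p000032","e0000032",94,"female",1,"D003","E66","",FALSE,2007-06-20
"p000033","e0000033",76,"male",1,"D005","S72","K25",FALSE,2006-10-27
"p000034","e0000034",71,"female",9,"D005","E66","K704;N390",FALSE,2005-07-20
"p000035","e0000035",84,"female",16,"D004","K59","",FALSE,2005-07-08
"p000036","e0000036",75,"male",13,"D001","I10","G81",FALSE,2006-03-01
"p000037","e0000037",50,"male",7,"D005","I10","B20",FALSE,2005-12-30
"p000038","e0000038",57,"male",7,"D004","M17","K703",TRUE,2006-09-05
"p000039","e0000039",67,"female",2,"D002","H25","",FALSE,2006-06-26
"p000040","e0000040",101,"male",15,"D004","S72","",FALSE,2007-06-17
"p000041","e0000041",64,"female",1,"D005","M17","G30",FALSE,2006-03-27
"p000042","e0000042",50,"male",1,"D002","S72","B20;F05",FALSE,2006-11-21
"p000043","e0000043",103,"male",26,"D005","K59","L89",FALSE,2006-05-24
"p000044","e0000044",87,"female",3,"D003","H25","G81;I21",FALSE,2007-02-03
"p000045","e0000045",104,"male",14,"D002","M17","I70;G30",FALSE,2006-09-18
"p000046","e0000046",92,"male",1,"D005","M17","I21;N390",TRUE,2005-08-22
"p000047","e0000047",68,"female",1,"D005","S72","",FALSE,2006-02-16
"p000048","e0000048",95,"female",9,"D001","A09","B20;K25",FALSE,2005-07-08
"p000049","e0000049",97,"male",19,"D001","H25","",TRUE,2007-03-11
"p000050","e0000050",58,"female",1,"D005","I10","K25;C18",FALSE,2006-06-16
"p000051","e0000051",93,"female",3,"D004","H25","",FALSE,2006-11-08
"p000052","e0000052",101,"female",3,"D005","A09","K704",FALSE,2006-07-04
"p000053","e0000053",76,"female",12,"D003","S72","K704",FALSE,2007-05-05
"p000054","e0000054",105,"female",3,"D004","M17","J13",FALSE,2007-04-27
"p000055","e0000055",81,"female",8,"D003","M54","",FALSE,2006-08-07
"p000056","e0000056",93,"male",6,"D004","R07","I60;F05",FALSE,2005-11-15
"p000057","e0000057",52,"male",6,"D003","A09","J18",FALSE,2005-10-13
"p000058","e0000058",69,"male",11,"D002","E66","",FALSE,2005-10-11
"p000059","e0000059",65,"female",1,"D002","I10","",FALSE,2006-11-20
"p000060","e0000060",81,"female",1,"D004","I10","K704;J18",TRUE,2007-01-20
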