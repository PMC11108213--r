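arm,group,replicate,assay,value
AC,control,1,Bradford_A595,0.3387095844714667
DC,control,1,Bradford_A595,0.3193530182860391
AC,120,1,Bradford_A595,0.35863128411337336
DC,120,1,Bradford_A595,0.35332862604961046
AC,180,1,Bradford_A595,0.38904268323141
DC,180,1,Bradford_A595,0.36793875483908517
AC,240,1,Bradford_A595,0.4301152199743894
DC,240,1,Bradford_A595,0.39005340961586904
AC,control,2,Bradford_A595,0.34518423713877044
DC,control,2,Bradford_A595,0.3243728590094758
AC,120,2,Bradford_A595,0.3680486965422348
DC,120,2,Bradford_A595,0.3698664539270111
AC,180,2,Bradford_A595,0.37111139298887663
DC,180,2,Bradford_A595,0.36621211233182627
AC,240,2,Bradford_A595,0.4136667866360634
DC,240,2,Bradford_A595,0.39735950398070075
AC,control,3,Bradford_A595,0.3221574707858393
DC,control,3,Bradford_A595,0.29843544579095227
AC,120,3,Bradford_A595,0.3305953307142448
DC,120,3,Bradford_A595,0.360201133457302
AC,180,3,Bradford_A595,0.3819336140592153
DC,180,3,Bradford_A595,0.3511869156602
AC,240,3,Bradford_A595,0.41328082644240377
DC,240,3,Bradford_A595,0.403146746991726
AC,control,4,Bradford_A595,0.34395193461264967
DC,control,4,Bradford_A595,0.32069530868393803
AC,120,4,Bradford_A595,0.35242730617231066
DC,120,4,Bradford_A595,0.32936836914805223
AC,180,4,Bradford_A595,0.38960097354831275
DC,180,4,Bradford_A595,0.3626000512403988
AC,240,4,Bradford_A595,0.41955450123241217
DC,240,4,Bradford_A595,0.3980483733722882
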